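---
title: "Hypothesis testing on differentially private synthetic data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypothesis testing on differentially private synthetic data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpsynthtest)
```

## The question the package answers

Differentially private (DP) synthetic data are often proposed as a safe
release mechanism for sensitive biomedical data: an analyst receives a
synthetic dataset and runs ordinary statistics on it, and the DP
post-processing property guarantees that nothing they compute weakens the
privacy bound. The statistical question is whether those ordinary analyses
remain *trustworthy*. For an independent-sample hypothesis test two things
can break: the test can reject true null hypotheses far more often than its
significance level promises (inflated Type I error — false discoveries), or
it can lose so much power that real effects disappear (Type II error near 1).

`dpsynthtest` provides the machinery to measure both failure modes under
controlled conditions: generators with a *known* null and a *known* effect
size, three DP synthesizers operating on group-by-value histograms, a DP
Mann–Whitney (MW) U test run directly on the sensitive data as the
best-known-power reference, the four classical tests with explicit
feasibility rules, and a repetition harness that turns rejection counts into
error-rate estimates.

## Differential privacy, as used here

A randomized mechanism $M$ is $(\epsilon, \delta)$-DP if for all outputs $S$
and all neighboring datasets $D, D'$ differing in one row,
$\Pr[M(D) \in S] \le e^{\epsilon} \Pr[M(D') \in S] + \delta$. For
$\delta = 0$ this says the log-probability of any outcome moves by at most
$\epsilon$ between neighbors. The package verifies this *directly* for its
two simplest mechanisms: the test suite enumerates every outcome of the
smoothed histogram on tiny domains, and every pre-clipping noise vector of
the perturbed histogram, and checks
$|\log \Pr_D(\text{outcome}) - \log \Pr_{D'}(\text{outcome})| \le \epsilon$
exhaustively. For MWEM, whose outcome space is too rich to enumerate, the
guarantee follows from sequential composition, and the fitted object exposes
its per-iteration budget split so the accounting can be checked.

Neighboring datasets are replace-one (same $n$). A two-group histogram
therefore has $L_1$ sensitivity 2 — moving one record changes two cells by
one each — which is why the perturbed histogram's discrete Laplace noise has
scale $2/\epsilon$.

## The three synthesizers

**Perturbed histogram.** Each cell of the $2 \times B$ joint histogram
receives independent discrete Laplace noise ($\Pr(k) \propto e^{-|k|/b}$,
$b = 2/\epsilon$), negative counts are set to zero, and one record per unit
of count is emitted at the bin center. The synthetic size is the sum of the
clipped noisy counts, so it is only "around" $n$: with many empty cells the
clipping is biased upward (a property the tests check by simulation). The
zero-clipping is also the mechanism behind the false discoveries this
synthesizer produces at small $\epsilon$: both group rows acquire
independent noise floors, and with a sample of bin-center records drawn from
two *different* noisy rows the MW test sees a systematic group difference
that was never in the data.

**Smoothed histogram.** Cell probabilities are
$p_i \propto c_i + 2m/\epsilon$ and exactly $m$ records are drawn i.i.d.
from them. Privacy comes from the additive smoothing term: moving one
record changes each per-draw probability by a factor at most
$1 + \epsilon/(2m)$, so $m$ draws change by at most $e^{\epsilon/2}$. The
same term is why utility degrades with $m$: the method is only used in the
regime $m \ll n$ (a warning fires at $m > n/10$). At strong privacy both
group rows are pulled toward the *same* near-uniform distribution, so the
two synthetic groups stay exchangeable and the MW test stays valid — the
price is power, not validity.

**MWEM.** Maintains a synthetic distribution $A$ over the domain cells,
initialized uniform. Each of $T$ iterations selects the worst-approximated
query from the workload (all one-way and two-way marginal cells; each is a
sensitivity-1 counting query) via the exponential mechanism with budget
$\epsilon/(2T)$, measures it with Laplace noise of scale $2T/\epsilon$, and
applies the multiplicative-weights update
$A(x) \leftarrow A(x) \exp\!\big(q(x)(m_t - q(nA))/(2n)\big)$, renormalized.
As in the standard practical form of the algorithm, the update is cycled
`mw_update_reps` times over the full measurement history each round; this
touches only already-released noisy answers, so it is free post-processing.

Two defaults deserve justification, because the design was genuinely open:

* `T = 30` and `mw_update_reps = 20`. These match the defaults of the
  widely used open-source MWEM implementations. They also matter
  scientifically: with a single update per iteration and small $T$ the
  fitted distribution barely leaves uniform at moderate noise, which makes
  the synthetic groups exchangeable by accident and *hides* the method's
  characteristic failure. With the standard history-cycling fit the
  distribution actually chases its noisy measurements, and spurious
  group-by-value structure — the source of MWEM's inflated Type I error —
  survives into the synthetic sample. Both knobs are exposed.
* The budget split is the canonical half selection / half measurement per
  iteration: $T(\epsilon/2T + \epsilon/2T) = \epsilon$.

## The DP Mann–Whitney U test

The reference baseline runs on the sensitive data itself. With total size
$N$ public: (i) a `size_fraction` share of $\epsilon$ (default 0.65, with
all of $\delta$, default $10^{-6}$) privatizes the smaller group size as
$\tilde n = \lceil n_1 + \mathrm{Lap}(1/\epsilon_1) +
\ln(1/2\delta)/\epsilon_1 \rceil$, clamped to $[1, \lfloor N/2 \rfloor]$;
(ii) the U statistic of the smaller group receives Laplace noise with scale
$\tilde n / \epsilon_2$ (one replaced record shifts U by at most the smaller
group size, and the released $\tilde n$ over-covers it with probability
$1-\delta$); (iii) the p-value is the two-sided add-one Monte-Carlo tail
probability, $p = \min(1,\, 2\min(\text{lower}, \text{upper}))$ with each
tail $(r+1)/(\text{reps}+1)$, against a reference distribution of U values
computed on random rank splits at the privatized sizes, each with fresh
Laplace noise at the same scale.

The add-one correction makes the Monte-Carlo p-value valid by construction;
the rejection rule everywhere in the package is the strict $p < \alpha$,
which keeps that validity exact. Reference distributions are cached per
$(\tilde n, N - \tilde n, \text{scale}, \text{reps})$; the default
resolution is 2,000 draws, a deliberate trade of runtime against Monte-Carlo
granularity (the smallest attainable p-value is $1/2001$).

The clamp at $\lfloor N/2 \rfloor$ is a deliberate design point. The
conservative offset is what delivers the $(1-\delta)$ over-coverage, but at
small $N$ it is large relative to the group size (about 20 at
$\epsilon_1 = 0.65$), and an uncapped $\tilde n$ skews the privatized split —
the null reference's mean $\tilde n (N - \tilde n)/2$ then sits well below
the observed statistic's null center and the test rejects in the upper tail
far too often. Since the smaller of two groups can never exceed
$\lfloor N/2 \rfloor$ and $N$ is public, the cap is deterministic
post-processing: it costs no budget, preserves the over-coverage, and
restores validity at every size.

## The classical tests and feasibility

The MW U statistic is the half-tie-counted pair count
$U = \#\{x_i < y_j\} + \tfrac12 \#\{x_i = y_j\}$, computed from midranks (so
$U_{xy} + U_{yx} = n_1 n_2$ holds exactly). Its p-value uses the normal
approximation with tie and continuity corrections *at all sample sizes* —
matching the default behavior of the standard scientific-computing routine
this kind of pipeline relies on — rather than switching to an exact method
at small $n$. The cost is documented, not hidden: against the exhaustive
permutation distribution the approximation deviates by up to about 0.09 at
group sizes (2,2) and about 0.03 at (4,4); at (3,3) it is within 0.02
wherever the exact p is at or below 0.5. The suite pins this down by
enumeration.

The t-test is the classic pooled-variance form (a `welch` flag is provided);
the chi-squared test applies the Yates continuity correction on 2×2 tables
(a flag disables it); the median test dichotomizes at the grand median with
ties counted as "not above" and then applies the corrected chi-squared test.
Both Yates-corrected tests are conservative at moderate $n$ — their null
rejection rates sit visibly below 0.05 — which the calibration tests treat
as what it is: validity with conservatism, not miscalibration.

Feasibility is explicit and machine-readable, never a silent `NA`: any empty
group fails every test (the dominant failure on DP-synthetic data, which
often collapses to a single class at small $\epsilon$); the t-test
additionally needs both groups of size two with nonzero pooled variance; the
MW and median tests need the pooled values not to be all tied (the median
test, more precisely, a non-degenerate group-by-median table). A result is
either feasible with a p-value or infeasible with a reason.

## What the generators emulate — and what they do not

**Gaussian two-group data** is the controlled population: null mode draws
both groups from $N(50, 2)$; signal mode draws $N(50,1)$ vs $N(51,1)$, an
effect of exactly one population standard deviation. Values are discretized
to 100 integer-labelled unit bins (clipped into $[0.5, 100.5)$) for the
histogram-based synthesizers. Bins are half-open $[l, r)$ with the last bin
closed by clipping; a bin's "center" is the midpoint of its edges. These
conventions are choices — the underlying design fixes only "100 bins ranging
from 1 to 100" — made so that integer values land in the bin of their own
label.

**The copula patient simulator** stands in for a clinical prostate-cancer
cohort: a 5-dimensional latent Gaussian with correlation matrix $R$ drives
age (normal, 65 ± 7 years), PSA ($120 \cdot \mathrm{Beta}(1.5, 8)$ ng/mL),
prostate volume ($200 \cdot \mathrm{Beta}(2, 6)$ mL), 5-ARI medication
(binary, thresholded latent, 15% prevalence), and PI-RADS score (ordinal
1–5, thresholded latent). Signal mode gives the high-risk half a latent
mean shift (largest on PSA and PI-RADS); null mode generates everyone from
the low-risk parameters and randomly relabels exactly half, so the groups
are exchangeable *by construction* — that exchangeability is the ground
truth that makes Type I error measurable at all. All parameters are
invented stand-ins, clearly exposed in `copula_spec()`: they preserve the
statistical structure such an analysis assumes (mixed types, moderate
positive PSA–PIRADS–label association, a known null) and deliberately do
not claim to match any real cohort. Passing tests on these generators
therefore demonstrate properties of the *methods* under realistic structure,
not agreement with any particular hospital's data.

**Real CSV data** enter through `read_two_group_csv()` (with BMI computed
from weight and height before the 24-bin BMI discretization). The package
ships no real data.

## The evaluation harness

`run_cell()` is one experimental condition: per repetition, draw an original
dataset, optionally synthesize under DP (or run the DP-MW test directly),
run the test if feasible, and count a rejection at $p < \alpha$
($\alpha = 0.05$ default). Under the null the rejection proportion estimates
Type I error; under signal the non-rejection proportion estimates Type II.
Proportions are conditioned on feasible repetitions and flagged `reported`
only when at least 50 repetitions were feasible — below that the estimate is
still emitted but marked untrustworthy, mirroring how heavily imbalanced or
single-class synthetic datasets are handled in practice.

Per-repetition seeds derive deterministically from (master seed, cell key,
repetition index), so cells are independent, reproducible in any execution
order, and resumable. `run_grid()` takes the Cartesian product of an
`experiment_config()` — the full two-group study design (4 DP methods × 5
budgets × 5 sizes × 2 modes) enumerates 200 cells — and returns one tidy row
per cell. The smoothed histogram follows its own design: a fresh $n =
20{,}000$ original dataset per repetition with synthetic sizes in
$\{50, 100, 500, 1000\}$, because its utility depends on $m \ll n$.

Problem sizes in the shipped test suite are the package's own choices: the
headline validity and inflation checks run at the study's full 500–1,000
repetitions, while supporting property checks use 100–500 repetitions with
correspondingly wider binomial slack (always $3\sqrt{p(1-p)/\text{reps}}$),
and the multivariate MWEM path is exercised on coarse bin configurations
(hundreds of cells) rather than the full 640,000-cell default domain.

## Known limitations

* No private selection of bin widths or counts: discretizations are fixed
  inputs, as in the underlying design.
* The MW p-value's normal approximation is documented to deviate from the
  exact permutation p at very small groups (see above); the package
  prioritizes faithfulness to the standard pipeline over small-sample
  exactness.
* The DP-ratio property is verified exhaustively only for the two histogram
  mechanisms on small domains; MWEM's guarantee rests on composition, not
  enumeration.
* The copula simulator's parameters are stand-ins; conclusions about any
  real cohort require fitting a simulator to that cohort, which is out of
  scope.
* Private-PGM and DP-GAN synthesizers are not implemented; the comparison
  set is the three histogram/marginal-based methods plus the DP-MW
  baseline.
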
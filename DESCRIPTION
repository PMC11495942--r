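Package: dpsynthtest
Title: Validity and Power of Hypothesis Tests on Differentially Private
    Synthetic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for assessing whether independent-sample
    hypothesis tests remain valid (Type I error at most the significance
    level) and powerful (low Type II error) when carried out on
    differentially private (DP) synthetic data instead of the original
    sensitive data.  Implements three histogram-based DP synthesizers
    (perturbed histogram with discrete Laplace noise, smoothed histogram,
    and the Multiplicative Weights Exponential Mechanism), a differentially
    private Mann-Whitney U test run directly on the sensitive data as a
    power reference, the classical Mann-Whitney U, Student's t, median and
    chi-squared tests with explicit feasibility rules, generators for
    two-group Gaussian data and a Gaussian-copula multivariate patient
    simulator with known null and signal modes, and an experiment harness
    that estimates Type I and Type II error proportions over repeated
    simulation with feasibility conditioning.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
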
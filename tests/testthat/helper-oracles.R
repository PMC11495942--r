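# Independent oracles used across the suite.  These deliberately use the
# slowest, most literal formulation of each quantity so they stay independent
# of the implementation paths they check.

# U statistic by brute-force pair enumeration, ties as one half
brute_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi < yj) + 0.5 * (xi == yj)
  u
}

# exact two-sided permutation p-value of the MW U test: probability, over all
# splits of the pooled values into groups of the observed sizes, of a U at
# least as far from its null mean as the observed one
perm_mw_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  ctr <- n1 * length(y) / 2
  splits <- utils::combn(length(pool), n1)
  us <- apply(splits, 2, function(ix) brute_u(pool[ix], pool[-ix]))
  u_obs <- brute_u(x, y)
  mean(abs(us - ctr) >= abs(u_obs - ctr) - 1e-9)
}

# pooled-variance two-sample t statistic and p-value by the hand formula
pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Yates-corrected chi-squared statistic for a 2x2 table by the hand formula
yates_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (abs(a * d - b * c) - n / 2)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# all count vectors over `cells` cells summing to n (for DP enumeration)
compositions <- function(n, cells) {
  if (cells == 1L) return(matrix(n, 1L, 1L))
  out <- NULL
  for (k in 0:n) {
    rest <- compositions(n - k, cells - 1L)
    out <- rbind(out, cbind(k, rest))
  }
  unname(out)
}

# exact probability that m iid draws from `p` produce the outcome sequence
# counts `ks` (unordered outcome: multinomial)
multinom_prob <- function(ks, p) {
  exp(lgamma(sum(ks) + 1) - sum(lgamma(ks + 1)) + sum(ks * log(p)))
}

# worst |log probability ratio| of the smoothed histogram over all outcomes
# and all neighboring count vectors at total n, domain of 2 cells
smoothed_worst_log_ratio <- function(n, m, epsilon) {
  worst <- 0
  for (a in 0:(n - 1)) {
    c1 <- c(a, n - a); c2 <- c(a + 1, n - a - 1)  # one record moved
    p1 <- dpsynthtest::smoothed_histogram_probs(c1, epsilon, m)
    p2 <- dpsynthtest::smoothed_histogram_probs(c2, epsilon, m)
    for (k in 0:m) {
      ks <- c(k, m - k)
      worst <- max(worst, abs(log(multinom_prob(ks, p1)) -
                              log(multinom_prob(ks, p2))))
    }
  }
  worst
}

# worst |log probability ratio| of the perturbed histogram's pre-clip noisy
# count vector over neighboring 2-cell histograms, outcomes with |noise|<=30
perturbed_worst_log_ratio <- function(c1, c2, epsilon, noise_range = 30L) {
  b <- 2 / epsilon
  worst <- 0
  for (v1 in (min(c1[1], c2[1]) - noise_range):(max(c1[1], c2[1]) + noise_range))
    for (v2 in (min(c1[2], c2[2]) - noise_range):(max(c1[2], c2[2]) + noise_range)) {
      lp1 <- sum(log(dpsynthtest::ddlaplace(c(v1, v2) - c1, b)))
      lp2 <- sum(log(dpsynthtest::ddlaplace(c(v1, v2) - c2, b)))
      worst <- max(worst, abs(lp1 - lp2))
    }
  worst
}

# binomial slack: 3 standard errors of a proportion p0 at `reps` repetitions
binom_slack <- function(p0, reps) 3 * sqrt(p0 * (1 - p0) / reps)
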
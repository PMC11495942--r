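#' Test result container
#'
#' Common return type of every hypothesis test in the package: statistic,
#' p-value, test name, and an explicit feasibility flag.  An infeasible
#' result never carries a p-value.
#'
#' @param statistic numeric test statistic (NA when infeasible).
#' @param p_value p-value in `[0, 1]` (NA when infeasible).
#' @param test_name short test identifier.
#' @param feasible logical.
#' @param reason machine-readable infeasibility reason, `""` when feasible.
#' @return an object of class `dp_test_result`.
#' @export
test_result <- function(statistic, p_value, test_name, feasible = TRUE,
                        reason = "") {
  if (feasible) {
    stopifnot(is.finite(statistic), is.finite(p_value),
              p_value >= 0, p_value <= 1)
  } else {
    statistic <- NA_real_
    p_value <- NA_real_
  }
  structure(list(statistic = as.numeric(statistic),
                 p_value = as.numeric(p_value),
                 test_name = test_name, feasible = isTRUE(feasible),
                 reason = reason),
            class = "dp_test_result")
}

#' @export
print.dp_test_result <- function(x, ...) {
  if (x$feasible)
    cat(sprintf("%s: statistic = %g, p-value = %.4g\n", x$test_name,
                x$statistic, x$p_value))
  else
    cat(sprintf("%s: infeasible (%s)\n", x$test_name, x$reason))
  invisible(x)
}

#' Mann-Whitney U statistic
#'
#' The number of cross-group pairs in which the first group's member is
#' smaller than the second group's, ties counted as one half:
#' `U = #\{(i,j): x_i < y_j\} + 0.5 * #\{(i,j): x_i = y_j\}`.
#' Computed from midranks, so it is exact including ties and satisfies
#' `u_statistic(x, y) + u_statistic(y, x) = |x| * |y|`.
#'
#' @param x,y nonempty numeric vectors.
#' @return the U statistic of `x` against `y`.
#' @export
u_statistic <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be nonempty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  rank_sum_x <- sum(r[seq_len(n1)])
  # rank_sum_x - n1(n1+1)/2 counts pairs with x > y (ties as half)
  n1 * n2 - (rank_sum_x - n1 * (n1 + 1) / 2)
}

#' Configuration of the DP Mann-Whitney U test
#'
#' @param epsilon positive total privacy budget.
#' @param delta probability of exceeding the budget, in `(0, 1)`;
#'   default `1e-6`.
#' @param size_fraction fraction of epsilon spent on privatizing the smaller
#'   group size, in `(0, 1)`; default 0.65.
#' @param null_mc_reps Monte-Carlo draws for the null reference distribution
#'   (at least 100); default 2000.
#' @return an object of class `dpmw_config`.
#' @export
dpmw_config <- function(epsilon, delta = 1e-6, size_fraction = 0.65,
                        null_mc_reps = 2000L) {
  stopifnot(epsilon > 0, delta > 0, delta < 1,
            size_fraction > 0, size_fraction < 1)
  null_mc_reps <- as.integer(null_mc_reps)
  if (null_mc_reps < 100L) stop("null_mc_reps below 100 is rejected")
  structure(list(epsilon = epsilon, delta = delta,
                 size_fraction = size_fraction,
                 null_mc_reps = null_mc_reps),
            class = "dpmw_config")
}

#' Privatize the smaller group size
#'
#' Adds Laplace noise at scale `1/epsilon_1` plus the conservative offset
#' `ln(1/(2*delta))/epsilon_1`, then takes the ceiling and clamps at zero.
#' The offset is chosen so that the released estimate falls below the true
#' size with probability at most `delta`.
#'
#' @param n_small true size of the smaller group (non-negative integer).
#' @param epsilon_1 positive budget share.
#' @param delta real in `(0, 1)`.
#' @return a non-negative integer size estimate.
#' @export
privatize_smaller_group_size <- function(n_small, epsilon_1, delta) {
  stopifnot(n_small >= 0, epsilon_1 > 0, delta > 0, delta < 1)
  offset <- log(1 / (2 * delta)) / epsilon_1
  est <- n_small + rlaplace(1L, 1 / epsilon_1) + offset
  max(0L, as.integer(ceiling(est)))
}

# Per-session cache of null reference distributions
.ref_cache <- new.env(parent = emptyenv())

#' Monte-Carlo null reference distribution of the noisy U statistic
#'
#' Draws `reps` values of U computed on a uniformly random split of the ranks
#' `1..(n1+n2)` into groups of sizes `n1` and `n2`, each plus Laplace noise
#' at `noise_scale`.  Results are cached per `(n1, n2, noise_scale, reps)`,
#' so repeated calls with identical keys return the identical vector.
#'
#' @param n1,n2 positive group sizes.
#' @param noise_scale non-negative Laplace scale added to each draw.
#' @param reps number of draws, at least 100.
#' @return sorted numeric vector of length `reps`.
#' @export
null_reference_distribution <- function(n1, n2, noise_scale, reps) {
  n1 <- as.integer(n1); n2 <- as.integer(n2); reps <- as.integer(reps)
  stopifnot(n1 >= 1L, n2 >= 1L, noise_scale >= 0)
  if (reps < 100L) stop("reps below 100 is rejected")
  key <- paste(n1, n2, format(noise_scale, digits = 17), reps, sep = "|")
  if (!is.null(.ref_cache[[key]])) return(.ref_cache[[key]])
  N <- n1 + n2
  base <- n1 * n2 + n1 * (n1 + 1) / 2
  u <- vapply(seq_len(reps),
              function(i) base - sum(sample.int(N, n1)),
              numeric(1))
  out <- sort(u + rlaplace(reps, noise_scale))
  .ref_cache[[key]] <- out
  out
}

#' Clear the cached null reference distributions
#' @return invisibly, the number of entries removed.
#' @export
clear_reference_cache <- function() {
  n <- length(ls(.ref_cache))
  rm(list = ls(.ref_cache), envir = .ref_cache)
  invisible(n)
}

#' Differentially private Mann-Whitney U test
#'
#' Runs directly on the sensitive data and releases an (epsilon, delta)-DP
#' statistic and p-value.  A `size_fraction` share of epsilon (with all of
#' delta) privatizes the smaller group size; the U statistic of the smaller
#' group against the larger then receives Laplace noise with scale equal to
#' the privatized smaller size divided by the remaining budget (one record
#' change can shift U by at most the smaller group size).  The p-value is the
#' two-sided add-one Monte-Carlo tail probability of the noisy U under
#' [null_reference_distribution()] at the privatized group sizes, which makes
#' it valid by construction.  The total sample size N is treated as public;
#' since the smaller group can never exceed `floor(N/2)`, the privatized size
#' is capped there (deterministic post-processing), which keeps the null
#' reference centred correctly at small N where the conservative offset is
#' large relative to the group size.
#'
#' @param sample a [two_group_sample()].
#' @param config a [dpmw_config()].
#' @return a [test_result()] with `test_name = "dp_mw"`.
#' @export
dp_mw_u_test <- function(sample, config) {
  stopifnot(inherits(sample, "two_group_sample"), inherits(config, "dpmw_config"))
  if (sample$n1 == 0L || sample$n2 == 0L)
    return(test_result(NA, NA, "dp_mw", feasible = FALSE,
                       reason = "empty_group"))
  small <- if (sample$n1 <= sample$n2) 0L else 1L
  x <- group_values(sample, small)
  y <- group_values(sample, 1L - small)
  n_total <- length(x) + length(y)

  eps1 <- config$size_fraction * config$epsilon
  eps2 <- (1 - config$size_fraction) * config$epsilon
  n_tilde <- privatize_smaller_group_size(length(x), eps1, config$delta)
  # free post-processing with the public total: the smaller group can never
  # exceed floor(N/2), and both privatized sizes must be usable group sizes.
  # Without this cap the conservative offset skews the small-sample null
  # reference (its mean n1*n2/2 shrinks as the split grows more unequal).
  n_tilde <- min(max(n_tilde, 1L), as.integer(n_total %/% 2L))
  scale <- n_tilde / eps2

  u_noisy <- u_statistic(x, y) + rlaplace(1L, scale)
  ref <- null_reference_distribution(n_tilde, n_total - n_tilde, scale,
                                     config$null_mc_reps)
  reps <- length(ref)
  lower <- (sum(ref <= u_noisy) + 1) / (reps + 1)
  upper <- (sum(ref >= u_noisy) + 1) / (reps + 1)
  p <- min(1, 2 * min(lower, upper))
  test_result(u_noisy, p, "dp_mw")
}
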
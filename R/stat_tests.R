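#' Mann-Whitney U test (normal approximation)
#'
#' Two-sided test of the null hypothesis that both groups are drawn from the
#' same distribution, using the asymptotic normal approximation with tie
#' correction and continuity correction at all sample sizes.  The reported
#' statistic is [u_statistic()] of `x` against `y`.
#'
#' @param x,y numeric vectors.
#' @return a [test_result()] with `test_name = "mwu"`.
#' @export
mw_u_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    return(test_result(NA, NA, "mwu", FALSE, "empty_group"))
  if (length(unique(c(x, y))) == 1L)
    return(test_result(NA, NA, "mwu", FALSE, "all_values_tied"))
  u <- u_statistic(x, y)
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  if (!is.finite(p))
    return(test_result(NA, NA, "mwu", FALSE, "degenerate_rank_variance"))
  test_result(u, p, "mwu")
}

#' Student's t-test (equal variances)
#'
#' Classic pooled-variance two-sample t-test of equal means, two-sided.
#' Infeasible when a group has fewer than two records or the pooled variance
#' is zero.  `welch = TRUE` switches to the Welch unequal-variance form.
#'
#' @param x,y numeric vectors.
#' @param welch use the Welch correction instead of pooling?
#' @return a [test_result()] with `test_name = "ttest"`.
#' @export
t_test <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    return(test_result(NA, NA, "ttest", FALSE, "group_too_small"))
  if (stats::var(x) + stats::var(y) == 0)
    return(test_result(NA, NA, "ttest", FALSE, "zero_variance"))
  ht <- stats::t.test(x, y, var.equal = !welch)
  test_result(unname(ht$statistic), ht$p.value, "ttest")
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' With Yates continuity correction by default (df = 1, two-sided).
#' Infeasible when any row or column marginal is zero.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param correct apply the Yates correction?
#' @return a [test_result()] with `test_name = "chi2"`.
#' @export
chi_squared_test <- function(table, correct = TRUE) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table < 0)) stop("negative cell counts")
  if (sum(table) == 0)
    return(test_result(NA, NA, "chi2", FALSE, "empty_table"))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(test_result(NA, NA, "chi2", FALSE, "zero_marginal"))
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  test_result(unname(ht$statistic), ht$p.value, "chi2")
}

#' Median test
#'
#' Tabulates each group above / not-above the grand median (ties count as
#' not-above) and applies the 2x2 chi-squared test to the resulting table.
#' Infeasible when a row or column of that table is all zero, e.g. when every
#' value ties the grand median.
#'
#' @param x,y numeric vectors.
#' @return a [test_result()] with `test_name = "median"`.
#' @export
median_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    return(test_result(NA, NA, "median", FALSE, "empty_group"))
  tab <- median_table(x, y)
  res <- chi_squared_test(tab)
  if (!res$feasible) return(test_result(NA, NA, "median", FALSE, res$reason))
  test_result(res$statistic, res$p_value, "median")
}

#' Group-by-median contingency table
#'
#' The 2x2 table underlying [median_test()]: rows are groups, columns count
#' values strictly above vs not above the grand median of the pooled data.
#'
#' @param x,y numeric vectors.
#' @return 2x2 integer matrix.
#' @export
median_table <- function(x, y) {
  med <- stats::median(c(x, y))
  matrix(c(sum(x > med), sum(x <= med),
           sum(y > med), sum(y <= med)),
         nrow = 2L, byrow = TRUE,
         dimnames = list(c("x", "y"), c("above", "not_above")))
}

#' Feasibility of a test on a two-group sample
#'
#' Tests on DP-synthetic data can be undefined, most commonly when the
#' synthesizer emits a single-class dataset.  This predicate applies the
#' per-test requirements without running the test: any empty group is
#' infeasible for all tests; the t-test additionally needs both groups of
#' size at least two with nonzero pooled variance; the MW U and median tests
#' need the pooled values not to be all tied; the chi-squared rule is
#' evaluated on the group-by-median table, matching how the harness
#' dichotomizes a continuous value.
#'
#' @param sample a [two_group_sample()].
#' @param test_name one of `"mwu"`, `"ttest"`, `"median"`, `"chi2"`.
#' @return list with elements `feasible` (logical) and `reason` (character).
#' @export
check_feasibility <- function(sample, test_name) {
  stopifnot(inherits(sample, "two_group_sample"),
            test_name %in% c("mwu", "ttest", "median", "chi2"))
  if (sample$n1 == 0L || sample$n2 == 0L)
    return(list(feasible = FALSE, reason = "empty_group"))
  x <- group_values(sample, 0L); y <- group_values(sample, 1L)
  if (test_name == "ttest") {
    if (length(x) < 2L || length(y) < 2L)
      return(list(feasible = FALSE, reason = "group_too_small"))
    if (stats::var(x) + stats::var(y) == 0)
      return(list(feasible = FALSE, reason = "zero_variance"))
  } else if (test_name == "mwu") {
    if (length(unique(c(x, y))) == 1L)
      return(list(feasible = FALSE, reason = "all_values_tied"))
  } else {  # median, chi2: need a non-degenerate 2x2 table
    tab <- median_table(x, y)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      return(list(feasible = FALSE, reason = "zero_marginal"))
  }
  list(feasible = TRUE, reason = "")
}
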
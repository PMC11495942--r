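make_hist <- function(counts, lower = 0, upper = ncol(counts)) {
  joint_histogram(counts, bin_spec(ncol(counts), lower, upper))
}

test_that("perturbed histogram recovers the original counts without noise", {
  set.seed(1)
  h <- build_joint_histogram(gaussian_two_group(500, "null"), gaussian_bins())
  syn <- perturbed_histogram_synthesize(h, privacy_budget(1e6))
  expect_identical(matrix(as.integer(syn$noisy_counts), 2), unclass(h$counts))
  expect_equal(length(syn$sample$labels), h$n)
  expect_error(perturbed_histogram_synthesize(h, privacy_budget(1, 1e-6)),
               "delta")
})

test_that("zero-clipping of empty cells biases the synthetic size upward", {
  # a sparse histogram: one nonzero cell among 20; clipping the negative
  # noise in the 19 empty cells adds positive mass on average
  counts <- matrix(0L, 2, 10)
  counts[1, 1] <- 20L
  h <- make_hist(counts)
  set.seed(2)
  sizes <- replicate(2000, {
    syn <- perturbed_histogram_synthesize(h, privacy_budget(0.1))
    length(syn$sample$labels)
  })
  expect_gt(mean(sizes), h$n)
})

test_that("perturbed-histogram noise vector satisfies the epsilon-DP ratio", {
  # exhaustive enumeration over neighboring 2-cell histograms
  for (eps in c(0.5, 1, 2)) {
    worst <- perturbed_worst_log_ratio(c(3, 1), c(2, 2), eps)
    expect_lte(worst, eps + 1e-9)
  }
  # the bound is tight-ish: at eps = 1 the worst ratio is close to eps
  expect_gt(perturbed_worst_log_ratio(c(3, 1), c(2, 2), 1), 0.5)
})

test_that("smoothed histogram probabilities follow c_i + 2m/eps", {
  expect_equal(smoothed_histogram_probs(c(0, 0), 1, 5), c(0.5, 0.5))
  expect_equal(smoothed_histogram_probs(c(10, 0), 2, 1), c(11 / 12, 1 / 12))
  # smoothing vanishes as eps -> Inf: empirical distribution recovered
  expect_equal(smoothed_histogram_probs(c(3, 1), 1e12, 1), c(0.75, 0.25),
               tolerance = 1e-9)
  expect_true(all(smoothed_histogram_probs(c(0, 5, 0), 0.1, 100) > 0))
})

test_that("smoothed histogram sampling satisfies the epsilon-DP ratio", {
  # exhaustive outcomes, all neighboring datasets with n <= 4, m <= 2
  for (eps in c(0.5, 1, 2))
    for (n in 1:4)
      for (m in 1:2)
        expect_lte(smoothed_worst_log_ratio(n, m, eps), eps + 1e-9)
})

test_that("smoothed synthesizer emits m near-uniform records at small eps", {
  set.seed(3)
  h <- build_joint_histogram(gaussian_two_group(20000, "null"),
                             gaussian_bins())
  syn <- smoothed_histogram_synthesize(h, privacy_budget(0.1), 500)
  expect_equal(length(syn$sample$labels), 500L)
  # both synthetic groups closer to uniform over bins than the original data
  tv_uniform <- function(v, spec) {
    tab <- tabulate(discretize(v, spec) + 1L, spec$n_bins)
    sum(abs(tab / sum(tab) - 1 / spec$n_bins)) / 2
  }
  for (g in 0:1) {
    tv_syn <- tv_uniform(group_values(syn$sample, g), gaussian_bins())
    tv_orig <- tv_uniform(group_values(
      records_from_counts(h$counts, gaussian_bins()), g), gaussian_bins())
    expect_lt(tv_syn, tv_orig)
  }
  # the regime warning fires when m is not small relative to n
  expect_warning(smoothed_histogram_synthesize(h, privacy_budget(1), 5000),
                 "considerably smaller")
})

test_that("MWEM validates inputs and handles the degenerate domain", {
  expect_error(mwem(array(5, 1), privacy_budget(1), T = 0), "positive")
  fit <- mwem(array(5, dim = 1), privacy_budget(1), T = 1)
  expect_equal(as.numeric(fit$weights), 1)
})

test_that("MWEM reproduces measured marginals in the no-noise limit", {
  counts <- matrix(c(40, 10, 5, 25, 15, 5, 30, 20), nrow = 2)
  set.seed(4)
  fit <- mwem(counts, privacy_budget(1e6), T = 10, mw_update_reps = 500)
  # every measured marginal of n*A agrees with the true marginal within 1%
  n <- sum(counts)
  dims <- dim(counts)
  for (i in seq_len(nrow(fit$trace))) {
    S <- as.integer(strsplit(fit$trace$marginal[i], "x")[[1]])
    tr_true <- apply(counts, S, sum)
    tr_fit <- apply(fit$weights * n, S, sum)
    k <- fit$trace$cell[i]
    # row-major flattening over S matches the trace's cell numbering
    flat_true <- as.vector(aperm(array(tr_true, dims[S]), rev(seq_along(S))))
    flat_fit <- as.vector(aperm(array(tr_fit, dims[S]), rev(seq_along(S))))
    expect_equal(flat_fit[k], flat_true[k], tolerance = 0.01)
  }
})

test_that("MWEM weights stay a probability distribution and budgets add up", {
  set.seed(5)
  h <- build_joint_histogram(gaussian_two_group(200, "null"),
                             bin_spec(10, 40, 60, TRUE, TRUE))
  fit <- mwem(h, privacy_budget(2), T = 7)
  expect_true(all(fit$weights >= 0))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  expect_equal(nrow(fit$trace), 7L)
  expect_equal(fit$T * (fit$eps_select_per_iter + fit$eps_measure_per_iter),
               fit$budget$epsilon, tolerance = 1e-12)
})

test_that("MWEM is deterministic given the seed and sampling is faithful", {
  h <- build_joint_histogram(
    two_group_sample(rep(0:1, each = 20), rep(c(0.5, 1.5), 20)),
    bin_spec(2, 0, 2))
  set.seed(6); f1 <- mwem(h, privacy_budget(1), T = 5)
  set.seed(6); f2 <- mwem(h, privacy_budget(1), T = 5)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$trace, f2$trace)

  # uniform weights: each cell frequency 0.5 within 3 standard errors
  f1$weights <- matrix(c(0.5, 0.5, 0, 0), 2)
  f1$bin_spec <- NULL
  set.seed(7)
  cells <- mwem_sample(f1, 1e5)
  expect_lt(abs(mean(cells == 1) - 0.5), 3 * sqrt(0.25 / 1e5))

  # point mass: all records identical
  f1$weights <- matrix(c(0, 0, 1, 0), 2)
  f1$bin_spec <- bin_spec(2, 0, 2)
  syn <- mwem_sample(f1, 50)
  expect_true(all(syn$sample$labels == 0L))
  expect_true(all(syn$sample$values == 1.5))
  expect_error(mwem_sample(f1, 0), "positive")
})

test_that("workload queries enumerate one- and two-way marginals", {
  wl <- marginal_workload(3)
  expect_length(wl, 3 + 3)
  expect_length(marginal_workload(1), 1)
})
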
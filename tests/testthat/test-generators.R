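test_that("Gaussian generator hits the stated moments and split", {
  set.seed(15)
  s <- gaussian_two_group(20000, "null")
  expect_equal(s$n1, 10000L)
  expect_lt(abs(mean(s$values) - 50), 3 * 2 / sqrt(20000))

  sig <- gaussian_two_group(20000, "signal")
  diff <- mean(group_values(sig, 1)) - mean(group_values(sig, 0))
  expect_lt(abs(diff - 1), 3 * sqrt(2 / 10000))

  expect_equal(gaussian_two_group(50)$n1, 25L)
  expect_equal(gaussian_two_group(51)$n1, 26L)  # round half up
  expect_error(gaussian_two_group(1), "at least 2")
})

test_that("copula spec validates and simulation respects marginals", {
  expect_error(copula_spec(R = diag(5) * 2), "diag")
  bad <- matrix(0.99, 5, 5); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.99
  expect_error(copula_spec(R = bad), "positive definite")

  set.seed(16)
  df <- copula_simulate(copula_spec(), 4000, "signal")
  expect_equal(sum(df$label), 2000L)
  expect_true(all(df$pirads %in% 1:5))
  expect_true(all(df$ari5 %in% 0:1))
  expect_true(all(df$psa >= 0 & df$psa <= 120))
  expect_true(all(df$volume >= 0 & df$volume <= 200))
  # the signal shifts raise PSA and PI-RADS in the high-risk class
  expect_gt(mean(df$psa[df$label == 1]), mean(df$psa[df$label == 0]))
  expect_gt(mean(df$pirads[df$label == 1]), mean(df$pirads[df$label == 0]))
  expect_error(copula_simulate(copula_spec(), 7), "even")
})

test_that("identity latent correlation gives independent variables", {
  set.seed(17)
  spec <- copula_spec(R = diag(5))
  df <- copula_simulate(spec, 1e5, "null")
  cors <- cor(cbind(df$age, df$psa, df$volume, df$pirads))
  off <- cors[upper.tri(cors)]
  expect_true(all(abs(off) < 3 / sqrt(1e5) * 2))  # rank-ish transforms shrink r
})

test_that("null-mode copula groups are exchangeable: tests stay valid", {
  # scaled-down calibration on the raw simulated multivariate data
  slack <- binom_slack(0.05, 300)
  for (tst in c("mwu", "ttest")) {
    r <- run_cell("copula", "null", "none", n = 100, test = tst,
                  reps = 300, seed = 22)
    expect_lte(r$proportion, 0.05 + slack)
  }
})

test_that("zero shifts make signal mode marginally identical to null mode", {
  spec <- copula_spec(shifts = rep(0, 5))
  set.seed(18)
  a <- copula_simulate(spec, 3000, "signal")
  b <- copula_simulate(spec, 3000, "null")
  # with zero shifts the high- and low-risk classes coincide in distribution
  expect_gt(mw_u_test(a$psa[a$label == 1], a$psa[a$label == 0])$p_value, 0.01)
  expect_gt(suppressWarnings(
    stats::ks.test(a$psa, b$psa)$p.value), 0.001)
  expect_lt(abs(mean(a$pirads) - mean(b$pirads)), 0.1)
})

test_that("multivariate discretization is a bijection with the PSA tail rule", {
  cfg <- mv_bin_config()
  df <- data.frame(age = c(55, 101), psa = c(55, 2.2), volume = c(30, 250),
                   ari5 = c(0L, 1L), pirads = c(3L, 5L), label = c(0L, 1L))
  d <- discretize_multivariate(df, cfg)
  expect_equal(d$dims, c(20L, 40L, 20L, 2L, 5L, 2L), ignore_attr = TRUE)
  # PSA >= 40 is in the last PSA bin
  expect_equal(d$bins[1, "psa"], 39L, ignore_attr = TRUE)
  # index -> tuple -> index round trip
  expect_equal(mv_index_to_bins(d$index, d$dims), unname(d$bins))
  # two binary variables: index = 2*v1 + v2
  cfg2 <- mv_bin_config(age = bin_spec(2, 0, 2), psa = bin_spec(2, 0, 2),
                        volume = bin_spec(2, 0, 2), pirads = bin_spec(2, 0, 2))
  df2 <- data.frame(age = c(1.5, 0.5), psa = c(0.5, 1.5),
                    volume = c(0.5, 0.5), ari5 = c(0L, 0L),
                    pirads = c(0.5, 0.5), label = c(0L, 0L))
  d2 <- discretize_multivariate(df2, cfg2)
  b <- unname(d2$bins)
  manual <- b[, 1]
  for (v in 2:6) manual <- manual * d2$dims[v] + b[, v]
  expect_equal(d2$index, as.integer(manual))
  # domain-size cap
  expect_error(discretize_multivariate(df, cfg, max_cells = 100), "cap")
})

test_that("counts array and record reconstruction are consistent", {
  cfg <- mv_bin_config(age = bin_spec(4, 40, 90, TRUE, TRUE),
                       psa = bin_spec(4, 0, 40, TRUE, TRUE),
                       volume = bin_spec(3, 0, 200, TRUE, TRUE))
  set.seed(19)
  df <- copula_simulate(copula_spec(), 500, "signal")
  arr <- mv_counts_array(df, cfg)
  expect_equal(sum(arr), 500)
  expect_equal(dim(arr), unname(mv_dims(cfg)))
  # one-way label marginal of the array equals the true class balance
  expect_equal(as.vector(apply(arr, 6, sum)), c(250, 250))
  # cells -> records -> cells round trip through bin centers
  cells <- sample.int(prod(dim(arr)), 200, replace = TRUE)
  rec <- mv_records_from_cells(cells, cfg)
  rt <- discretize_multivariate(rec, cfg)
  lin <- rep(0, 200)
  for (v in rev(seq_along(rt$dims))) lin <- lin * rt$dims[v] + rt$bins[, v]
  expect_equal(as.integer(lin) + 1L, cells)
})
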
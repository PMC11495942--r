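test_that("discretize maps values to half-open bins and clips per spec", {
  # PSA of 55 lands in the last of 40 bins when overflow is clipped
  expect_equal(discretize(55, bin_spec(40, 1, 40, overflow_to_last = TRUE)),
               39L)
  expect_equal(discretize(55, psa_bins()), 39L)
  # the left edge of the first bin is bin 0
  expect_equal(discretize(1, bin_spec(99, 1, 100)), 0L)
  # unit-width binning: 1.99 stays left of the edge, 2.0 crosses it
  expect_equal(discretize(c(1.0, 1.99, 2.0), bin_spec(99, 1, 100)),
               c(0L, 0L, 1L))
  # every interior edge belongs to the bin on its right
  spec <- bin_spec(10, 0, 5)
  edges <- spec$lower + (1:9) * bin_width(spec)
  expect_equal(discretize(edges, spec), 1:9)
  # out-of-range values error, naming the offender, when clipping is off
  expect_error(discretize(-1, spec), "below.*-1")
  expect_error(discretize(5, spec), "above.*5")
  # clipping sends them to the boundary bins instead
  both <- bin_spec(10, 0, 5, TRUE, TRUE)
  expect_equal(discretize(c(-3, 99), both), c(0L, 9L))
})

test_that("joint histogram counts by (group, bin) cell and conserves totals", {
  spec <- bin_spec(4, 0, 4)
  s <- two_group_sample(c(0, 1), c(0, 0))
  h <- build_joint_histogram(s, spec)
  expect_equal(h$counts[1, 1], 1L)
  expect_equal(h$counts[2, 1], 1L)
  expect_equal(h$n, 2L)

  # an empty group leaves its row all zero
  s2 <- two_group_sample(rep(0, 5), c(0.1, 1.2, 2.3, 3.4, 0.9))
  h2 <- build_joint_histogram(s2, spec)
  expect_true(all(h2$counts[2, ] == 0L))
  expect_equal(sum(h2$counts), 5L)

  # six records in six distinct cells give six ones
  s3 <- two_group_sample(c(0, 0, 0, 1, 1, 1), c(0.5, 1.5, 2.5, 0.5, 1.5, 3.5))
  h3 <- build_joint_histogram(s3, spec)
  expect_equal(sort(as.vector(h3$counts)), c(0L, 0L, rep(1L, 6)))

  # conservation for random samples
  set.seed(42)
  for (i in 1:10) {
    n <- sample(1:200, 1)
    s <- two_group_sample(rbinom(n, 1, 0.5), runif(n, 0, 4))
    expect_equal(build_joint_histogram(s, spec)$n, n)
  }
})

test_that("records_from_counts emits bin-center records and round-trips", {
  spec <- bin_spec(3, 1, 4)  # unit bins, centers 1.5, 2.5, 3.5
  counts <- matrix(0L, 2, 3)
  counts[1, 1] <- 2L
  s <- records_from_counts(counts, spec)
  expect_equal(s$labels, c(0L, 0L))
  expect_equal(s$values, c(1.5, 1.5))

  empty <- records_from_counts(matrix(0L, 2, 3), spec)
  expect_equal(length(empty$labels), 0L)

  counts[2, 3] <- -1L
  expect_error(records_from_counts(counts, spec), "negative")

  # exact round trip: counts -> records -> counts
  set.seed(7)
  for (i in 1:10) {
    cm <- matrix(rpois(6, 3), 2, 3)
    rt <- build_joint_histogram(records_from_counts(cm, spec), spec)
    expect_identical(rt$counts, matrix(as.integer(cm), 2, 3))
  }
})

test_that("marginals sum to n and flatten row-major", {
  spec <- bin_spec(2, 0, 2)
  h <- joint_histogram(matrix(c(1L, 0L, 0L, 1L), 2, 2), spec)
  m1 <- marginals(h, 1)
  expect_equal(m1$group, c(1L, 1L))
  expect_equal(m1$bin, c(1L, 1L))
  expect_equal(marginals(h, 2)$joint, c(1L, 0L, 0L, 1L))
  expect_error(marginals(h, 3), "unsupported")

  set.seed(11)
  hh <- build_joint_histogram(
    two_group_sample(rbinom(60, 1, 0.4), runif(60, 0, 2)), spec)
  for (m in c(marginals(hh, 1), marginals(hh, 2)))
    expect_equal(sum(m), hh$n)
})

test_that("canonical bin specs realize the study discretizations", {
  g <- gaussian_bins()
  expect_equal(g$n_bins, 100L)
  expect_equal(bin_centers(g), as.numeric(1:100))  # integer-labelled bins
  expect_equal(discretize(c(0.2, 50, 101), g), c(0L, 49L, 99L))

  b <- bmi_bins()
  expect_equal(b$n_bins, 24L)
  expect_equal(discretize(c(12, 17.9, 18, 39.9, 40, 55), b),
               c(0L, 0L, 1L, 22L, 23L, 23L))

  p <- psa_bins()
  expect_equal(discretize(c(0.3, 39.9, 40, 200), p), c(0L, 38L, 39L, 39L))
})

test_that("two-group CSV round-trips and rejects malformed input", {
  s <- two_group_sample(c(0, 1, 1), c(1.5, 2.5, 3.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_two_group_csv(s, path)
  s2 <- read_two_group_csv(path)
  expect_equal(s2$labels, s$labels)
  expect_equal(s2$values, s$values)

  header_only <- withr::local_tempfile(fileext = ".csv")
  writeLines("group,value", header_only)
  expect_error(read_two_group_csv(header_only), "empty sample")

  bad_group <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("group,value", "2,1.0", "0,2.0"), bad_group)
  expect_error(read_two_group_csv(bad_group), "malformed")
})

test_that("BMI arithmetic uses metres squared", {
  expect_equal(bmi_from(70, 175), 70 / 1.75^2, tolerance = 1e-12)
  expect_equal(round(bmi_from(70, 175), 3), 22.857)
})
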
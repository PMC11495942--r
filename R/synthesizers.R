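#' @noRd
dp_synthetic <- function(sample, method, budget, requested_size = NA_integer_) {
  structure(list(sample = sample, method = method, budget = budget,
                 requested_size = requested_size),
            class = "dp_synthetic")
}

#' @export
print.dp_synthetic <- function(x, ...) {
  cat(sprintf("dp_synthetic (%s, epsilon = %g): ", x$method, x$budget$epsilon))
  print(x$sample)
  invisible(x)
}

#' DP perturbed-histogram synthesizer
#'
#' Adds an independent discrete-Laplace draw with scale `2/epsilon` to every
#' (group, bin) cell of the joint histogram, sets negative noisy counts to
#' zero, and emits one bin-center record per remaining unit of count.  Under
#' replace-one adjacency a joint histogram has L1 sensitivity 2, so the
#' pre-clipping noise vector is `epsilon`-DP; clipping and record emission are
#' post-processing.  The synthetic size is the sum of the clipped noisy
#' counts, hence "around" the original size.
#'
#' @param hist a `joint_histogram`.
#' @param budget a [privacy_budget()] with `delta = 0`.
#' @return a `dp_synthetic` object; `$noisy_counts` carries the clipped
#'   count matrix actually released.
#' @export
perturbed_histogram_synthesize <- function(hist, budget) {
  stopifnot(inherits(hist, "joint_histogram"), inherits(budget, "privacy_budget"))
  if (budget$delta != 0)
    stop("the perturbed histogram is a pure epsilon-DP mechanism; delta must be 0")
  b <- 2 / budget$epsilon
  noise <- matrix(rdlaplace(length(hist$counts), b), nrow = 2L)
  noisy <- pmax(hist$counts + noise, 0L)
  out <- dp_synthetic(records_from_counts(noisy, hist$bin_spec),
                      "perturbed_hist", budget)
  out$noisy_counts <- noisy
  out
}

#' Smoothed-histogram sampling probabilities
#'
#' Cell probabilities proportional to `c_i + 2 m / epsilon`, where `c_i` is
#' the original count in cell `i` and `m` is the number of synthetic records
#' that will be drawn.  The additive smoothing term is what makes drawing `m`
#' i.i.d. records from these probabilities `epsilon`-DP: moving one record
#' between cells changes each per-draw probability by a factor of at most
#' `1 + epsilon/(2m)`, so `m` draws change by at most `exp(epsilon/2)`.
#'
#' @param counts non-negative numeric vector of cell counts.
#' @param epsilon positive real.
#' @param m positive integer synthetic size.
#' @return probability vector summing to 1, all entries positive.
#' @export
smoothed_histogram_probs <- function(counts, epsilon, m) {
  stopifnot(length(counts) >= 1L, all(counts >= 0), epsilon > 0, m >= 1)
  w <- counts + 2 * m / epsilon
  w / sum(w)
}

#' DP smoothed-histogram synthesizer
#'
#' Draws `m` cells i.i.d. from [smoothed_histogram_probs()] over all
#' (group, bin) cells of the joint histogram and emits bin-center records.
#' The intended regime has `m` considerably smaller than the original size;
#' a warning is issued when `m > n/10`.
#'
#' @param hist a `joint_histogram`.
#' @param budget a [privacy_budget()].
#' @param m positive integer synthetic size.
#' @return a `dp_synthetic` object of exactly `m` records.
#' @export
smoothed_histogram_synthesize <- function(hist, budget, m) {
  stopifnot(inherits(hist, "joint_histogram"), inherits(budget, "privacy_budget"))
  m <- as.integer(m)
  if (m <= 0) stop("m must be a positive integer")
  if (m > hist$n / 10)
    warning("synthetic size m exceeds n/10; the smoothed histogram is ",
            "intended for m considerably smaller than the original size")
  flat <- as.vector(t(hist$counts))  # row-major: group 0 cells first
  p <- smoothed_histogram_probs(flat, budget$epsilon, m)
  cells <- sample.int(length(flat), m, replace = TRUE, prob = p)
  counts <- matrix(tabulate(cells, nbins = length(flat)), nrow = 2L, byrow = TRUE)
  out <- dp_synthetic(records_from_counts(counts, hist$bin_spec),
                      "smoothed_hist", budget, requested_size = m)
  out
}
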
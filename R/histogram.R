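#' Joint group-by-bin histogram
#'
#' Cross-tabulates a two-group sample over (group, value-bin) cells.  This is
#' the object every histogram-based DP synthesizer privatizes.
#'
#' @param sample a [two_group_sample()]; must be nonempty.
#' @param spec a [bin_spec()].
#' @return an object of class `joint_histogram`: a 2 x n_bins integer matrix
#'   of counts (row 1 = group 0, row 2 = group 1), the bin spec, and the
#'   total count `n`.
#' @export
build_joint_histogram <- function(sample, spec) {
  stopifnot(inherits(sample, "two_group_sample"), inherits(spec, "bin_spec"))
  if (length(sample$labels) == 0L) stop("sample is empty")
  bins <- discretize(sample$values, spec)
  counts <- matrix(0L, nrow = 2L, ncol = spec$n_bins)
  for (g in 0:1) {
    tb <- tabulate(bins[sample$labels == g] + 1L, nbins = spec$n_bins)
    counts[g + 1L, ] <- as.integer(tb)
  }
  joint_histogram(counts, spec)
}

#' Construct a joint histogram from a count matrix
#' @param counts 2 x n_bins matrix of non-negative integer counts.
#' @param spec a [bin_spec()] with matching `n_bins`.
#' @return an object of class `joint_histogram`.
#' @export
joint_histogram <- function(counts, spec) {
  stopifnot(is.matrix(counts), nrow(counts) == 2L,
            inherits(spec, "bin_spec"), ncol(counts) == spec$n_bins)
  if (any(counts < 0)) stop("negative counts are a contract violation")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, bin_spec = spec, n = sum(counts)),
            class = "joint_histogram")
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat(sprintf("joint_histogram: 2 x %d cells, n = %d (group 0: %d, group 1: %d)\n",
              ncol(x$counts), x$n, sum(x$counts[1L, ]), sum(x$counts[2L, ])))
  invisible(x)
}

#' Reconstruct record-level data from bin counts
#'
#' Emits, for every (group, bin) cell, `counts[g, b]` records labelled `g`
#' with value equal to the bin center point.
#'
#' @param counts 2 x n_bins non-negative integer matrix.
#' @param spec a [bin_spec()].
#' @return a [two_group_sample()] of size `sum(counts)`.
#' @export
records_from_counts <- function(counts, spec) {
  stopifnot(is.matrix(counts), nrow(counts) == 2L,
            inherits(spec, "bin_spec"), ncol(counts) == spec$n_bins)
  if (any(counts < 0)) stop("negative counts are a contract violation")
  if (any(counts != round(counts))) stop("counts must be integers")
  centers <- bin_centers(spec)
  labels <- c(rep.int(0L, sum(counts[1L, ])), rep.int(1L, sum(counts[2L, ])))
  values <- c(rep.int(centers, counts[1L, ]), rep.int(centers, counts[2L, ]))
  two_group_sample(labels, values)
}

#' Marginal count vectors of a joint histogram
#'
#' Order 1 returns the one-way marginals (group totals and bin totals); order
#' 2 returns the flattened joint cells (row-major, group 0 first).  Every
#' marginal sums to `hist$n`.
#'
#' @param hist a `joint_histogram`.
#' @param order 1 or 2.
#' @return a named list of integer vectors.
#' @export
marginals <- function(hist, order) {
  stopifnot(inherits(hist, "joint_histogram"))
  if (!order %in% c(1L, 2L)) stop("unsupported marginal order: ", order)
  if (order == 1L)
    list(group = as.integer(rowSums(hist$counts)),
         bin = as.integer(colSums(hist$counts)))
  else
    list(joint = as.integer(t(hist$counts)))
}
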
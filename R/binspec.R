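#' Uniform-width histogram bin specification
#'
#' Defines a partition of `[lower, upper)` into `n_bins` half-open bins of
#' equal width.  Values below `lower` are clipped into the first bin when
#' `underflow_to_first` is `TRUE`; values at or above `upper` are clipped into
#' the last bin when `overflow_to_last` is `TRUE`; otherwise out-of-range
#' values are an error.
#'
#' @param n_bins number of bins, at least 2.
#' @param lower,upper real bounds of the binned range, `lower < upper`.
#' @param underflow_to_first clip values below `lower` into bin 1?
#' @param overflow_to_last clip values at or above `upper` into the last bin?
#' @return an object of class `bin_spec`.
#' @seealso [discretize()], [gaussian_bins()], [psa_bins()], [bmi_bins()]
#' @export
bin_spec <- function(n_bins, lower, upper,
                     underflow_to_first = FALSE, overflow_to_last = FALSE) {
  n_bins <- as.integer(n_bins)
  stopifnot(length(n_bins) == 1L, n_bins >= 2L,
            is.numeric(lower), is.numeric(upper), length(lower) == 1L,
            length(upper) == 1L, lower < upper,
            is.logical(underflow_to_first), is.logical(overflow_to_last))
  structure(list(n_bins = n_bins, lower = as.numeric(lower),
                 upper = as.numeric(upper),
                 underflow_to_first = isTRUE(underflow_to_first),
                 overflow_to_last = isTRUE(overflow_to_last)),
            class = "bin_spec")
}

#' @export
print.bin_spec <- function(x, ...) {
  w <- bin_width(x)
  cat(sprintf("bin_spec: %d bins of width %g on [%g, %g)%s%s\n",
              x$n_bins, w, x$lower, x$upper,
              if (x$underflow_to_first) ", underflow clipped" else "",
              if (x$overflow_to_last) ", overflow clipped" else ""))
  invisible(x)
}

#' Bin width of a bin specification
#' @param spec a [bin_spec()].
#' @return the common bin width.
#' @export
bin_width <- function(spec) (spec$upper - spec$lower) / spec$n_bins

#' Bin centers of a bin specification
#'
#' The "center point" of a bin is the arithmetic midpoint of its edges; it is
#' the value a synthesizer emits for a record placed in that bin.
#'
#' @param spec a [bin_spec()].
#' @return numeric vector of length `n_bins`.
#' @export
bin_centers <- function(spec) {
  w <- bin_width(spec)
  spec$lower + (seq_len(spec$n_bins) - 0.5) * w
}

#' Map values to bin indices
#'
#' Bins are half-open `[left, right)`: a value equal to an interior edge lands
#' in the bin to its right.  Indices are 0-based (`0 .. n_bins-1`), matching
#' the internal convention used throughout; reports use 1-based labels.
#'
#' @param values numeric vector.
#' @param spec a [bin_spec()].
#' @return integer vector of 0-based bin indices.
#' @export
discretize <- function(values, spec) {
  stopifnot(inherits(spec, "bin_spec"), is.numeric(values))
  w <- bin_width(spec)
  k <- floor((values - spec$lower) / w)
  below <- values < spec$lower
  above <- values >= spec$upper
  if (any(below) && !spec$underflow_to_first)
    stop("value below binning range with clipping disabled: ",
         format(values[below][1L]))
  if (any(above) && !spec$overflow_to_last)
    stop("value at or above binning range with clipping disabled: ",
         format(values[above][1L]))
  k[below] <- 0
  k[above] <- spec$n_bins - 1L
  # guard against floating-point spill just below the upper edge
  as.integer(pmin(pmax(k, 0), spec$n_bins - 1L))
}

#' Canonical bin specification for the two-group Gaussian experiments
#'
#' 100 unit-width bins with integer labels 1..100: values are clipped into
#' `[0.5, 100.5)` so that a value of exactly `k` falls in bin `k`.
#'
#' @return a [bin_spec()].
#' @export
gaussian_bins <- function() bin_spec(100L, 0.5, 100.5, TRUE, TRUE)

#' Canonical PSA bin specification
#'
#' 40 unit-width bins labelled 1..40 (ng/mL); PSA values of 40 or more fall in
#' the last bin and values below 1 in the first.
#'
#' @return a [bin_spec()].
#' @export
psa_bins <- function() bin_spec(40L, 1, 41, TRUE, TRUE)

#' Canonical BMI bin specification
#'
#' 24 unit-width bins: the first absorbs BMI below 18 and the last BMI of 40
#' or more, with unit-width interior bins between 18 and 40.
#'
#' @return a [bin_spec()].
#' @export
bmi_bins <- function() bin_spec(24L, 17, 41, TRUE, TRUE)
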
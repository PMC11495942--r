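#' Privacy budget
#'
#' An (epsilon, delta) pair governing every DP mechanism in the package:
#' epsilon bounds the privacy loss; delta is the small probability of
#' exceeding that bound (0 for pure epsilon-DP mechanisms).
#'
#' @param epsilon positive real.
#' @param delta real in `[0, 1)`; default 0.
#' @return an object of class `privacy_budget`.
#' @export
privacy_budget <- function(epsilon, delta = 0) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            is.numeric(delta), length(delta) == 1L, delta >= 0, delta < 1)
  structure(list(epsilon = as.numeric(epsilon), delta = as.numeric(delta)),
            class = "privacy_budget")
}

#' @export
print.privacy_budget <- function(x, ...) {
  cat(sprintf("privacy_budget: epsilon = %g, delta = %g\n", x$epsilon, x$delta))
  invisible(x)
}

#' Discrete Laplace (two-sided geometric) noise
#'
#' Integer-valued noise with `P(k)` proportional to `exp(-|k|/b)`, the
#' discrete analogue of the Laplace mechanism.  Sampled as the difference of
#' two i.i.d. geometric variables with success probability `1 - exp(-1/b)`.
#'
#' @param n number of draws.
#' @param b positive scale.
#' @return integer vector of length `n`.
#' @export
rdlaplace <- function(n, b) {
  stopifnot(b > 0)
  p <- 1 - exp(-1 / b)
  stats::rgeom(n, p) - stats::rgeom(n, p)
}

#' Probability mass function of the discrete Laplace distribution
#' @param k integer vector.
#' @param b positive scale.
#' @return `P(K = k)` with normalizer `(1 - t)/(1 + t)`, `t = exp(-1/b)`.
#' @export
ddlaplace <- function(k, b) {
  stopifnot(b > 0)
  t <- exp(-1 / b)
  (1 - t) / (1 + t) * t^abs(k)
}

#' Continuous Laplace noise
#' @param n number of draws.
#' @param scale positive scale (variance `2 * scale^2`).
#' @return numeric vector centred at 0.
#' @export
rlaplace <- function(n, scale) {
  stopifnot(scale >= 0)
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log1p(-2 * abs(u))
}
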
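#' Two-group Gaussian data generator
#'
#' The controlled population used to measure error rates.  In `"null"` mode
#' both groups are drawn from the same N(50, 2) distribution, so any
#' rejection is a Type I error.  In `"signal"` mode the groups are N(50, 1)
#' and N(51, 1) — an effect size of exactly one population standard
#' deviation — so any non-rejection is a Type II error.
#'
#' @param n total sample size, at least 2.
#' @param mode `"null"` or `"signal"`.
#' @param group_ratio fraction of records in group 0 (round-half-up);
#'   default 0.5.
#' @return a [two_group_sample()].
#' @export
gaussian_two_group <- function(n, mode = c("null", "signal"),
                               group_ratio = 0.5) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2")
  stopifnot(group_ratio > 0, group_ratio < 1)
  n1 <- as.integer(floor(n * group_ratio + 0.5))
  n1 <- min(max(n1, 1L), n - 1L)
  n2 <- n - n1
  if (mode == "null") {
    v1 <- stats::rnorm(n1, 50, 2)
    v2 <- stats::rnorm(n2, 50, 2)
  } else {
    v1 <- stats::rnorm(n1, 50, 1)
    v2 <- stats::rnorm(n2, 51, 1)
  }
  two_group_sample(c(rep.int(0L, n1), rep.int(1L, n2)), c(v1, v2))
}

#' Gaussian-copula patient simulator specification
#'
#' Parameterizes the multivariate stand-in for a prostate-cancer-like
#' dataset: a 5-dimensional latent Gaussian with correlation matrix `R`
#' drives age (normal), PSA and prostate volume (scaled beta), 5-ARI
#' medication (binary via a thresholded latent), and PI-RADS score (ordinal
#' 1-5 via thresholded latent).  The binary risk label is assigned by
#' design: in signal mode the high-risk class receives the latent mean
#' `shifts`, in null mode all records come from the low-risk parameters.
#' All defaults are invented stand-ins exposed for configuration; they
#' preserve the statistical structure (mixed types, moderate positive
#' PSA/PI-RADS/label association, a known null) without claiming to match
#' any real cohort.
#'
#' @param R 5x5 latent correlation matrix (age, psa, volume, ari5, pirads);
#'   must be symmetric positive definite with unit diagonal.
#' @param shifts length-5 latent mean shift applied to the high-risk class
#'   in signal mode.
#' @param age_mean,age_sd age marginal, years.
#' @param psa_scale,psa_shape1,psa_shape2 PSA in ng/mL as
#'   `psa_scale * Beta(psa_shape1, psa_shape2)`.
#' @param vol_scale,vol_shape1,vol_shape2 prostate volume in mL, likewise.
#' @param pirads_probs length-5 category probabilities for PI-RADS 1..5.
#' @param ari5_prev prevalence of 5-ARI use.
#' @return an object of class `copula_spec`.
#' @export
copula_spec <- function(R = NULL,
                        shifts = c(age = 0.2, psa = 0.8, volume = 0.1,
                                   ari5 = 0, pirads = 0.9),
                        age_mean = 65, age_sd = 7,
                        psa_scale = 120, psa_shape1 = 1.5, psa_shape2 = 8,
                        vol_scale = 200, vol_shape1 = 2, vol_shape2 = 6,
                        pirads_probs = c(0.15, 0.30, 0.25, 0.20, 0.10),
                        ari5_prev = 0.15) {
  if (is.null(R)) {
    R <- matrix(c(1.00, 0.15, 0.25, 0.20, 0.10,
                  0.15, 1.00, 0.30, 0.10, 0.45,
                  0.25, 0.30, 1.00, 0.25, 0.15,
                  0.20, 0.10, 0.25, 1.00, 0.05,
                  0.10, 0.45, 0.15, 0.05, 1.00), 5L, 5L)
  }
  stopifnot(is.matrix(R), all(dim(R) == 5L), isTRUE(all.equal(R, t(R))),
            all(diag(R) == 1))
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("latent correlation matrix is not positive definite")
  stopifnot(length(shifts) == 5L, age_sd > 0, psa_scale > 0, vol_scale > 0,
            psa_shape1 > 0, psa_shape2 > 0, vol_shape1 > 0, vol_shape2 > 0,
            length(pirads_probs) == 5L, all(pirads_probs > 0),
            abs(sum(pirads_probs) - 1) < 1e-8,
            ari5_prev > 0, ari5_prev < 1)
  structure(list(R = R, shifts = as.numeric(shifts),
                 age_mean = age_mean, age_sd = age_sd,
                 psa_scale = psa_scale, psa_shape1 = psa_shape1,
                 psa_shape2 = psa_shape2, vol_scale = vol_scale,
                 vol_shape1 = vol_shape1, vol_shape2 = vol_shape2,
                 pirads_probs = pirads_probs, ari5_prev = ari5_prev),
            class = "copula_spec")
}

.mvr <- function(n, mu, R) {
  z <- MASS::mvrnorm(n, mu = mu, Sigma = R)
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  z
}

# map latent normals (n x 5) to observed variables
.copula_transform <- function(z, spec) {
  pir_cuts <- stats::qnorm(cumsum(spec$pirads_probs)[-5L])
  data.frame(
    age = spec$age_mean + spec$age_sd * z[, 1L],
    psa = spec$psa_scale *
      stats::qbeta(stats::pnorm(z[, 2L]), spec$psa_shape1, spec$psa_shape2),
    volume = spec$vol_scale *
      stats::qbeta(stats::pnorm(z[, 3L]), spec$vol_shape1, spec$vol_shape2),
    ari5 = as.integer(z[, 4L] > stats::qnorm(1 - spec$ari5_prev)),
    pirads = findInterval(z[, 5L], pir_cuts) + 1L)
}

#' Simulate multivariate patient records from the Gaussian copula
#'
#' In `"signal"` mode exactly half of the records form the high-risk class,
#' generated with the class-conditional latent mean shift, so the classes
#' genuinely differ.  In `"null"` mode all records are generated from the
#' low-risk parameters and exactly half are then randomly relabelled
#' high-risk: the groups are exchangeable by construction, which is the
#' ground truth making Type I error measurable.
#'
#' @param spec a [copula_spec()].
#' @param n total number of records; must be even.
#' @param mode `"null"` or `"signal"`.
#' @return a data.frame with columns `age`, `psa`, `volume`, `ari5`,
#'   `pirads`, `label` (1 = high-risk).
#' @export
copula_simulate <- function(spec, n, mode = c("null", "signal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "copula_spec"))
  n <- as.integer(n)
  if (n < 2L || n %% 2L != 0L) stop("n must be an even integer >= 2")
  half <- n %/% 2L
  if (mode == "signal") {
    z_lo <- .mvr(half, rep(0, 5L), spec$R)
    z_hi <- .mvr(half, spec$shifts, spec$R)
    df <- .copula_transform(rbind(z_lo, z_hi), spec)
    df$label <- c(rep.int(0L, half), rep.int(1L, half))
  } else {
    z <- .mvr(n, rep(0, 5L), spec$R)
    df <- .copula_transform(z, spec)
    df$label <- 0L
    df$label[sample.int(n, half)] <- 1L
  }
  df
}
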
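#' Default bin configuration for the multivariate patient domain
#'
#' One [bin_spec()] per variable in the order `age`, `psa`, `volume`,
#' `ari5`, `pirads`, `label`.  Categorical variables use unit-width bins
#' centred on their categories, so bin centers reproduce the category values
#' exactly.  The default domain has `20 * 40 * 20 * 2 * 5 * 2 = 640,000`
#' cells; coarser specs keep MWEM runs cheap.
#'
#' @param age,psa,volume,ari5,pirads,label per-variable [bin_spec()]s.
#' @return a named list of class `mv_bin_config`.
#' @export
mv_bin_config <- function(age = bin_spec(20L, 40, 90, TRUE, TRUE),
                          psa = psa_bins(),
                          volume = bin_spec(20L, 0, 200, TRUE, TRUE),
                          ari5 = bin_spec(2L, -0.5, 1.5),
                          pirads = bin_spec(5L, 0.5, 5.5),
                          label = bin_spec(2L, -0.5, 1.5)) {
  cfg <- list(age = age, psa = psa, volume = volume, ari5 = ari5,
              pirads = pirads, label = label)
  stopifnot(all(vapply(cfg, inherits, TRUE, "bin_spec")))
  structure(cfg, class = "mv_bin_config")
}

#' Dimensions of a multivariate bin configuration
#' @param config an [mv_bin_config()].
#' @return integer vector of per-variable bin counts.
#' @export
mv_dims <- function(config) {
  stopifnot(inherits(config, "mv_bin_config"))
  vapply(config, function(s) s$n_bins, integer(1))
}

#' Discretize multivariate records into flattened domain cells
#'
#' Maps every record to a single cell index over the product domain of the
#' per-variable bins.  The exported index is the 0-based mixed-radix code
#' with the first variable most significant (two binary variables give
#' `index = 2 * v1 + v2`); the mapping between indices and per-variable bin
#' tuples is bijective.
#'
#' @param records data.frame with the columns named in `config`.
#' @param config an [mv_bin_config()].
#' @param max_cells refuse domains larger than this (default `1e6`).
#' @return list with `index` (0-based cell per record), `bins` (0-based
#'   per-variable bin matrix) and `dims`.
#' @export
discretize_multivariate <- function(records, config = mv_bin_config(),
                                    max_cells = 1e6) {
  stopifnot(inherits(config, "mv_bin_config"),
            all(names(config) %in% names(records)))
  dims <- mv_dims(config)
  if (prod(dims) > max_cells)
    stop(sprintf("domain size %.0f exceeds the configured cap of %.0f",
                 prod(dims), max_cells))
  bins <- vapply(names(config),
                 function(v) discretize(records[[v]], config[[v]]),
                 integer(nrow(records)))
  if (!is.matrix(bins)) bins <- matrix(bins, nrow = 1L,
                                       dimnames = list(NULL, names(config)))
  idx <- rep(0, nrow(records))
  for (v in seq_along(dims)) idx <- idx * dims[v] + bins[, v]
  list(index = as.integer(idx), bins = bins, dims = dims)
}

#' Invert a flattened multivariate cell index
#' @param index 0-based mixed-radix cell indices from
#'   [discretize_multivariate()].
#' @param dims per-variable bin counts.
#' @return 0-based per-variable bin matrix.
#' @export
mv_index_to_bins <- function(index, dims) {
  out <- matrix(0L, nrow = length(index), ncol = length(dims))
  rem <- as.integer(index)
  for (v in rev(seq_along(dims))) {
    out[, v] <- rem %% dims[v]
    rem <- rem %/% dims[v]
  }
  out
}

#' Multivariate counts as an array ready for [mwem()]
#' @param records data.frame of patient records.
#' @param config an [mv_bin_config()].
#' @param max_cells domain-size cap.
#' @return integer array with one dimension per variable.
#' @export
mv_counts_array <- function(records, config = mv_bin_config(),
                            max_cells = 1e6) {
  d <- discretize_multivariate(records, config, max_cells)
  dims <- d$dims
  # R-native column-major 0-based linear index (first variable fastest)
  lin <- rep(0, nrow(d$bins))
  for (v in rev(seq_along(dims))) lin <- lin * dims[v] + d$bins[, v]
  array(tabulate(as.integer(lin) + 1L, nbins = prod(dims)),
        dim = unname(dims))
}

#' Reconstruct patient records from sampled domain cells
#' @param cells 1-based linear cell indices over an array in the natural
#'   variable order (as produced by [mwem_sample()] on [mv_counts_array()]).
#' @param config an [mv_bin_config()].
#' @return data.frame of bin-center records.
#' @export
mv_records_from_cells <- function(cells, config = mv_bin_config()) {
  dims <- mv_dims(config)
  coords <- cells_to_coords(cells, dims)
  out <- lapply(seq_along(config), function(v)
    bin_centers(config[[v]])[coords[, v]])
  names(out) <- names(config)
  df <- as.data.frame(out)
  df$ari5 <- as.integer(round(df$ari5))
  df$pirads <- as.integer(round(df$pirads))
  df$label <- as.integer(round(df$label))
  df
}

#' Run one of the four tests on a multivariate patient dataset
#'
#' Applies the study's test-to-variable mapping: MW U on the ordinal PI-RADS
#' score, Student's t on age, median test on PSA, and the chi-squared test on
#' the label-by-5-ARI contingency table, always comparing the low- and
#' high-risk label groups.
#'
#' @param records data.frame with `age`, `psa`, `volume`, `ari5`, `pirads`,
#'   `label` columns.
#' @param test one of `"mwu"`, `"ttest"`, `"median"`, `"chi2"`.
#' @return a [test_result()].
#' @export
mv_run_test <- function(records, test = c("mwu", "ttest", "median", "chi2")) {
  test <- match.arg(test)
  g0 <- records$label == 0L
  if (all(g0) || !any(g0))
    return(test_result(NA, NA, test, FALSE, "single_class"))
  if (test == "mwu")
    mw_u_test(records$pirads[g0], records$pirads[!g0])
  else if (test == "ttest")
    t_test(records$age[g0], records$age[!g0])
  else if (test == "median")
    median_test(records$psa[g0], records$psa[!g0])
  else {
    tab <- matrix(c(sum(g0 & records$ari5 == 0L), sum(g0 & records$ari5 == 1L),
                    sum(!g0 & records$ari5 == 0L), sum(!g0 & records$ari5 == 1L)),
                  nrow = 2L, byrow = TRUE)
    chi_squared_test(tab)
  }
}
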
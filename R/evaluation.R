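#' Deterministic substream seeds
#'
#' Derives a 31-bit seed for one repetition of one grid cell from the master
#' seed and the cell key, so cells and repetitions are independent and
#' reproducible in any execution order.
#'
#' @param master master seed (integer).
#' @param cell_key character cell key (any length-1 string).
#' @param rep repetition number.
#' @return a positive integer below 2^31.
#' @export
substream_seed <- function(master, cell_key, rep) {
  M <- 2147483629
  h <- 0
  for (v in utf8ToInt(cell_key)) h <- (h * 131 + v) %% M
  h <- (h + (as.numeric(master) %% M) * 48271) %% M
  h <- (h * 69621 + as.numeric(rep) * 16807) %% M
  as.integer(h) + 1L
}

# run one classical test on a univariate two-group sample
run_two_group_test <- function(sample, test) {
  feas <- check_feasibility(sample, test)
  if (!feas$feasible) return(test_result(NA, NA, test, FALSE, feas$reason))
  x <- group_values(sample, 0L); y <- group_values(sample, 1L)
  switch(test,
         mwu = mw_u_test(x, y),
         ttest = t_test(x, y),
         median = median_test(x, y),
         chi2 = chi_squared_test(median_table(x, y)))
}

#' Estimate the error rate of one experimental condition
#'
#' One cell of the study grid: per repetition, draw an original dataset,
#' optionally pass it through a DP synthesizer (or the DP-MW U test run
#' directly on the sensitive data), run the test if feasible, and record a
#' rejection when `p < alpha`.  Under `mode = "null"` the rejection
#' proportion estimates the Type I error; under `mode = "signal"` the
#' non-rejection proportion estimates the Type II error.  The proportion is
#' conditioned on the feasible repetitions and flagged `reported` only when
#' at least 50 of them were feasible.
#'
#' @param generator `"gaussian"` or `"copula"`.
#' @param mode `"null"` or `"signal"`.
#' @param synthesizer one of `"none"`, `"dpmw"`, `"perturbed"`, `"smoothed"`,
#'   `"mwem"`.  The copula generator supports `"none"` and `"mwem"`.
#' @param epsilon privacy budget (ignored for `"none"`).
#' @param n original dataset size.
#' @param m synthetic dataset size; `NA` means match the original size.
#' @param test `"mwu"`, `"ttest"`, `"median"` or `"chi2"`.
#' @param reps number of repetitions.
#' @param alpha significance level.
#' @param seed master seed.
#' @param bins [bin_spec()] for the univariate histograms.
#' @param mwem_T MWEM iteration count.
#' @param dpmw_delta,dpmw_size_fraction,dpmw_reps DP-MW U test settings.
#' @param copula a [copula_spec()] for the multivariate generator.
#' @param mv_config an [mv_bin_config()] for the multivariate domain.
#' @return a one-row data.frame with columns `generator`, `mode`,
#'   `synthesizer`, `epsilon`, `n_original`, `n_synthetic`, `test`, `reps`,
#'   `feasible`, `rejections`, `proportion`, `reported`.
#' @export
run_cell <- function(generator = c("gaussian", "copula"),
                     mode = c("null", "signal"),
                     synthesizer = c("none", "dpmw", "perturbed", "smoothed",
                                     "mwem"),
                     epsilon = NA, n, m = NA, test = "mwu",
                     reps = 1000L, alpha = 0.05, seed = 1L,
                     bins = gaussian_bins(), mwem_T = 30L,
                     dpmw_delta = 1e-6, dpmw_size_fraction = 0.65,
                     dpmw_reps = 2000L,
                     copula = copula_spec(), mv_config = mv_bin_config()) {
  generator <- match.arg(generator)
  mode <- match.arg(mode)
  synthesizer <- match.arg(synthesizer)
  stopifnot(reps >= 1, alpha > 0, alpha < 1)
  if (synthesizer != "none" && !is.finite(epsilon))
    stop("epsilon required for synthesizer '", synthesizer, "'")
  if (generator == "copula" && !synthesizer %in% c("none", "mwem"))
    stop("the copula generator supports synthesizers 'none' and 'mwem'")
  if (synthesizer == "dpmw" && test != "mwu")
    stop("the DP-MW baseline is a Mann-Whitney test; use test = 'mwu'")

  key <- paste(generator, mode, synthesizer, epsilon, n, m, test, sep = "|")
  feasible <- 0L
  rejections <- 0L
  for (r in seq_len(reps)) {
    set.seed(substream_seed(seed, key, r))
    res <- tryCatch(
      one_repetition(generator, mode, synthesizer, epsilon, n, m, test,
                     bins, mwem_T, dpmw_delta, dpmw_size_fraction,
                     dpmw_reps, copula, mv_config),
      error = function(e) test_result(NA, NA, test, FALSE,
                                      paste0("error:", conditionMessage(e))))
    if (res$feasible) {
      feasible <- feasible + 1L
      if (res$p_value < alpha) rejections <- rejections + 1L
    }
  }
  data.frame(generator = generator, mode = mode, synthesizer = synthesizer,
             epsilon = as.numeric(epsilon), n_original = as.integer(n),
             n_synthetic = as.integer(if (is.na(m)) {
               if (synthesizer %in% c("none", "dpmw")) NA_integer_ else n
             } else m),
             test = test, reps = as.integer(reps), feasible = feasible,
             rejections = rejections,
             proportion = if (feasible > 0) rejections / feasible else NA_real_,
             reported = feasible >= 50L,
             stringsAsFactors = FALSE)
}

one_repetition <- function(generator, mode, synthesizer, epsilon, n, m, test,
                           bins, mwem_T, dpmw_delta, dpmw_size_fraction,
                           dpmw_reps, copula, mv_config) {
  if (generator == "gaussian") {
    s <- gaussian_two_group(n, mode)
    if (synthesizer == "none") return(run_two_group_test(s, test))
    if (synthesizer == "dpmw")
      return(dp_mw_u_test(s, dpmw_config(epsilon, dpmw_delta,
                                         dpmw_size_fraction, dpmw_reps)))
    h <- build_joint_histogram(s, bins)
    budget <- privacy_budget(epsilon)
    syn <- switch(synthesizer,
      perturbed = perturbed_histogram_synthesize(h, budget),
      smoothed = {
        if (is.na(m)) stop("the smoothed histogram needs an explicit ",
                           "synthetic size m")
        suppressWarnings(smoothed_histogram_synthesize(h, budget, m))
      },
      mwem = mwem_sample(mwem(h, budget, T = mwem_T),
                         if (is.na(m)) h$n else m))
    run_two_group_test(syn$sample, test)
  } else {
    df <- copula_simulate(copula, n, mode)
    if (synthesizer == "none") return(mv_run_test(df, test))
    arr <- mv_counts_array(df, mv_config)
    fit <- mwem(arr, privacy_budget(epsilon), T = mwem_T)
    cells <- mwem_sample(fit, if (is.na(m)) n else m)
    mv_run_test(mv_records_from_cells(cells, mv_config), test)
  }
}

#' Experiment configuration
#'
#' Bundles the grids of the study design: privacy budgets, original sizes,
#' synthetic sizes, tests, modes and synthesizers, plus repetitions,
#' significance level and the master seed.
#'
#' @param generator `"gaussian"` or `"copula"`.
#' @param modes subset of `c("null", "signal")`.
#' @param synthesizers subset of
#'   `c("none", "dpmw", "perturbed", "smoothed", "mwem")`.
#' @param epsilon_grid privacy budgets (default `c(0.01, 0.1, 1, 5, 10)`).
#' @param n_grid original sizes (default `c(50, 100, 500, 1000, 20000)`).
#' @param synthetic_sizes synthetic sizes, `NA` = match original.  The
#'   smoothed histogram's study design instead fixes `n = 20000` and draws
#'   sizes `c(50, 100, 500, 1000)`; pass them here for that synthesizer.
#' @param tests tests to run.
#' @param reps repetitions per cell (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed master seed.
#' @param ... extra arguments stored and forwarded to [run_cell()].
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(generator = "gaussian",
                              modes = c("null", "signal"),
                              synthesizers = "none",
                              epsilon_grid = c(0.01, 0.1, 1, 5, 10),
                              n_grid = c(50L, 100L, 500L, 1000L, 20000L),
                              synthetic_sizes = NA,
                              tests = "mwu",
                              reps = 1000L, alpha = 0.05, seed = 1L, ...) {
  stopifnot(length(epsilon_grid) >= 1L, length(n_grid) >= 1L,
            length(modes) >= 1L, length(synthesizers) >= 1L,
            length(tests) >= 1L, reps >= 1L, alpha > 0, alpha < 1)
  structure(list(generator = generator, modes = modes,
                 synthesizers = synthesizers, epsilon_grid = epsilon_grid,
                 n_grid = n_grid, synthetic_sizes = synthetic_sizes,
                 tests = tests, reps = as.integer(reps), alpha = alpha,
                 seed = as.integer(seed), extra = list(...)),
            class = "experiment_config")
}

#' Enumerate the grid cells of an experiment configuration
#'
#' The Cartesian product of modes, synthesizers, budgets, sizes and tests.
#' Synthesizer `"none"` ignores the epsilon grid (one cell per remaining
#' combination), matching how a non-private baseline enters the design.
#'
#' @param config an [experiment_config()].
#' @return data.frame with one row per cell.
#' @export
enumerate_cells <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cells <- expand.grid(mode = config$modes, synthesizer = config$synthesizers,
                       epsilon = config$epsilon_grid, n = config$n_grid,
                       m = config$synthetic_sizes, test = config$tests,
                       stringsAsFactors = FALSE)
  none <- cells$synthesizer == "none"
  if (any(none)) {
    cells$epsilon[none] <- NA
    cells <- unique(cells)
  }
  rownames(cells) <- NULL
  cells
}

#' Run the full experiment grid
#'
#' Runs [run_cell()] for every cell of [enumerate_cells()], deriving each
#' cell's substream seeds from the master seed, and binds the tidy one-row
#' results.  Re-running with the same configuration reproduces every
#' proportion exactly.
#'
#' @param config an [experiment_config()].
#' @param progress print one line per completed cell?
#' @return data.frame of error-rate estimates, one row per cell.
#' @export
run_grid <- function(config, progress = FALSE) {
  cells <- enumerate_cells(config)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    args <- c(list(generator = config$generator, mode = cl$mode,
                   synthesizer = cl$synthesizer, epsilon = cl$epsilon,
                   n = cl$n, m = cl$m, test = cl$test, reps = config$reps,
                   alpha = config$alpha, seed = config$seed),
              config$extra)
    out[[i]] <- do.call(run_cell, args)
    if (progress)
      cat(sprintf("[%d/%d] %s\n", i, nrow(cells),
                  paste(out[[i]][1, 1:7], collapse = " ")))
  }
  do.call(rbind, out)
}
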
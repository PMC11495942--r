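#' Marginal query workload
#'
#' The workload of linear counting queries used by [mwem()]: every cell of
#' every one-way and two-way marginal of a multi-dimensional count array.
#' Each such cell indicator has sensitivity 1 under replace-one adjacency.
#'
#' @param n_dims number of variables (array dimensions).
#' @param max_order highest marginal order to include (default 2).
#' @return an object of class `query_workload`: a list of integer vectors,
#'   each naming the dimensions of one marginal.
#' @export
marginal_workload <- function(n_dims, max_order = 2L) {
  stopifnot(n_dims >= 1L, max_order >= 1L)
  subsets <- lapply(seq_len(n_dims), function(d) d)
  if (max_order >= 2L && n_dims >= 2L) {
    pairs <- utils::combn(n_dims, 2L, simplify = FALSE)
    subsets <- c(subsets, pairs)
  }
  structure(subsets, class = "query_workload")
}

#' @export
print.query_workload <- function(x, ...) {
  cat(sprintf("query_workload: %d marginals (%s)\n", length(x),
              paste(vapply(x, function(s) paste(s, collapse = "x"), ""),
                    collapse = ", ")))
  invisible(x)
}

# 0-based marginal-cell assignment of every domain cell, for marginal over
# dimensions S (row-major over S in the order given)
marginal_assignment <- function(dims, S) {
  arr <- array(0L, dims)
  idx <- 0
  for (d in S) idx <- idx * dims[d] + (slice.index(arr, d) - 1L)
  as.integer(idx)
}

marginal_of <- function(v, assign, k_cells) {
  as.vector(rowsum(v, assign, reorder = TRUE))
}

#' Fit a synthetic distribution with the Multiplicative Weights Exponential
#' Mechanism
#'
#' MWEM maintains a distribution `A` over the discrete domain, initialized
#' uniform, and refines it for `T` iterations.  Each iteration (i) selects
#' the workload query with the largest absolute error on the current
#' synthetic distribution through the exponential mechanism (budget
#' `epsilon/(2T)`, utility `|q(D) - q(nA)|`, sensitivity 1), (ii) measures
#' the selected query with Laplace noise of scale `2T/epsilon` (budget
#' `epsilon/(2T)`), and (iii) applies the multiplicative-weights update
#' `A(x) <- A(x) * exp(q(x) * (m_t - q(nA)) / (2n))` followed by
#' renormalization.  As in the standard practical form of the algorithm (and
#' the public implementations of it), step (iii) cycles `mw_update_reps`
#' times over the full history of noisy measurements, so the synthetic
#' distribution is driven toward agreement with everything measured so far;
#' only the measurement history touches the sensitive data, so this
#' repetition is post-processing and costs no extra budget.  The
#' per-iteration selection and measurement budgets sum to `epsilon` by
#' sequential composition.
#'
#' @param x a `joint_histogram`, or an array/matrix of non-negative counts
#'   over a discrete domain.
#' @param budget a [privacy_budget()].
#' @param T number of iterations (default 30, the common implementation
#'   default).
#' @param workload a [marginal_workload()]; default all one-way and two-way
#'   marginals of the domain.
#' @param mw_update_reps multiplicative-weights passes over the measurement
#'   history per iteration (default 20).
#' @return an object of class `mwem`: the fitted `weights` array (summing to
#'   1), the measurement `trace` (one row per iteration: marginal id, marginal
#'   cell, noisy answer), the budget split, and the bin spec when fitted from
#'   a `joint_histogram`.
#' @seealso [mwem_sample()], [simulate.mwem()]
#' @export
mwem <- function(x, budget, T = 30L, workload = NULL, mw_update_reps = 20L) {
  stopifnot(inherits(budget, "privacy_budget"))
  T <- as.integer(T)
  mw_update_reps <- as.integer(mw_update_reps)
  if (T < 1L) stop("T must be a positive integer")
  if (mw_update_reps < 1L) stop("mw_update_reps must be a positive integer")
  spec <- NULL
  if (inherits(x, "joint_histogram")) {
    spec <- x$bin_spec
    counts <- x$counts
  } else counts <- x
  if (is.null(dim(counts))) dim(counts) <- length(counts)
  if (any(counts < 0)) stop("negative counts")
  dims <- dim(counts)
  n <- sum(counts)
  if (n < 1) stop("empty histogram")
  if (is.null(workload)) workload <- marginal_workload(length(dims))
  if (length(workload) == 0L) stop("empty workload")

  D <- prod(dims)
  cvec <- as.numeric(counts)
  assigns <- lapply(workload, function(S) marginal_assignment(dims, S))
  k_cells <- vapply(workload, function(S) prod(dims[S]), numeric(1))
  tD <- lapply(seq_along(workload),
               function(j) marginal_of(cvec, assigns[[j]], k_cells[j]))

  eps <- budget$epsilon
  eps_sel <- eps / (2 * T)   # exponential-mechanism budget per iteration
  meas_scale <- 2 * T / eps  # Laplace scale for the measurement

  w <- rep(1 / D, D)
  offsets <- cumsum(c(0, k_cells[-length(k_cells)]))
  trace <- data.frame(iteration = integer(T), marginal = character(T),
                      cell = integer(T), noisy_answer = numeric(T),
                      stringsAsFactors = FALSE)
  measured <- vector("list", T)
  for (t in seq_len(T)) {
    tA <- lapply(seq_along(workload),
                 function(j) n * marginal_of(w, assigns[[j]], k_cells[j]))
    err <- abs(unlist(tD) - unlist(tA))
    score <- eps_sel * err / 2
    p <- exp(score - max(score))
    pick <- sample.int(length(err), 1L, prob = p)
    j <- findInterval(pick - 1L, offsets)      # which marginal
    k <- pick - offsets[j]                     # 1-based cell within it
    m_t <- tD[[j]][k] + rlaplace(1L, meas_scale)
    measured[[t]] <- list(ind = assigns[[j]] == (k - 1L), answer = m_t)
    # post-processing: cycle the MW update over the measurement history
    for (pass in seq_len(mw_update_reps)) {
      for (mm in measured[seq_len(t)]) {
        est <- n * sum(w[mm$ind])
        w[mm$ind] <- w[mm$ind] * exp((mm$answer - est) / (2 * n))
        w <- w / sum(w)
      }
    }
    trace$iteration[t] <- t
    trace$marginal[t] <- paste(workload[[j]], collapse = "x")
    trace$cell[t] <- k
    trace$noisy_answer[t] <- m_t
  }
  dim(w) <- dims
  structure(list(weights = w, n = n, T = T, budget = budget,
                 eps_select_per_iter = eps_sel,
                 eps_measure_per_iter = eps / (2 * T),
                 mw_update_reps = mw_update_reps,
                 workload = workload, trace = trace, bin_spec = spec),
            class = "mwem")
}

#' @export
print.mwem <- function(x, ...) {
  cat(sprintf(
    "mwem fit: %s domain, n = %d, T = %d, epsilon = %g (%g per iteration)\n",
    paste(dim(x$weights), collapse = " x "), x$n, x$T, x$budget$epsilon,
    x$budget$epsilon / x$T))
  invisible(x)
}

#' Sample synthetic records from a fitted MWEM distribution
#'
#' Draws `m` domain cells i.i.d. from the fitted weights.  For a fit over a
#' (group x bin) joint histogram the cells are converted to bin-center
#' records; for a general array domain the 1-based linear cell indices are
#' returned with the domain dimensions attached.
#'
#' @param state an [mwem()] fit.
#' @param m positive integer number of records.
#' @return a `dp_synthetic` object (joint-histogram domains) or an integer
#'   vector of cell indices with a `dims` attribute.
#' @export
mwem_sample <- function(state, m) {
  stopifnot(inherits(state, "mwem"))
  m <- as.integer(m)
  if (m <= 0) stop("m must be a positive integer")
  D <- length(state$weights)
  cells <- sample.int(D, m, replace = TRUE, prob = as.numeric(state$weights))
  if (!is.null(state$bin_spec)) {
    counts <- matrix(tabulate(cells, nbins = D), nrow = 2L)
    return(dp_synthetic(records_from_counts(counts, state$bin_spec),
                        "mwem", state$budget, requested_size = m))
  }
  structure(cells, dims = dim(state$weights))
}

#' Simulate method for MWEM fits
#' @param object an [mwem()] fit.
#' @param nsim number of synthetic datasets.
#' @param seed optional seed passed to [set.seed()].
#' @param m records per dataset (default the original size `n`).
#' @param ... ignored.
#' @return a list of `nsim` draws from [mwem_sample()].
#' @export
simulate.mwem <- function(object, nsim = 1, seed = NULL, m = object$n, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) mwem_sample(object, m))
}

#' Convert linear cell indices to per-dimension coordinates
#' @param cells 1-based linear indices (as returned by [mwem_sample()]).
#' @param dims domain dimensions.
#' @return integer matrix, one row per cell, 1-based coordinates.
#' @export
cells_to_coords <- function(cells, dims) arrayInd(as.integer(cells), dims)
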
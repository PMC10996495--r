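#' Initialize a Poisson GLM-PCA model
#'
#' The initialization phase: choose the rank K and the covariate structure,
#' and build a starting [poispca_model].  Gene and cell factors are filled
#' with i.i.d. normal(0, 0.1) draws from the seeded generator; per-gene
#' intercepts start at `log((rowSums(Y) + 1) / (ncol(Y) + 1))` (a smoothed
#' log mean), and all other coefficients at zero.  Deterministic given
#' `seed`.
#'
#' @param Y Count matrix, genes by cells (anything [as_count_matrix()]
#'   accepts).
#' @param K Rank of the low-rank term; `0 <= K <= min(n, m)`.
#' @param gene_covariates Optional numeric matrix of known gene-level
#'   covariates (n rows); each gets an estimated coefficient per cell.
#' @param cell_covariates Optional numeric matrix of known cell-level
#'   covariates (m rows); each gets an estimated coefficient per gene.
#' @param gene_intercept Include a per-gene intercept (baseline log
#'   expression)?  Default `TRUE`.
#' @param cell_intercept Include a per-cell intercept (log size factor)?
#'   Default `TRUE`.
#' @param seed Integer seed for the factor initialization.
#' @return A `poispca_model` ready for [poispca_fit()].
#' @export
poispca_init <- function(Y, K, gene_covariates = NULL, cell_covariates = NULL,
                         gene_intercept = TRUE, cell_intercept = TRUE,
                         seed = 1L) {
  Y <- as_count_matrix(Y)
  n <- nrow(Y); m <- ncol(Y)
  K <- as.integer(K)
  if (is.na(K) || K < 0L || K > min(n, m))
    stop_config("rank K = %d must satisfy 0 <= K <= min(n, m) = %d",
                K, min(n, m))

  X <- build_covariates(cell_intercept, gene_covariates, n, "gene covariate")
  Z <- build_covariates(gene_intercept, cell_covariates, m, "cell covariate")
  if (ncol(X) > 0L && qr(X)$rank < ncol(X))
    stop_config("gene covariate matrix is rank deficient")
  if (ncol(Z) > 0L && qr(Z)$rank < ncol(Z))
    stop_config("cell covariate matrix is rank deficient")

  n_empty <- sum(Matrix::rowSums(Y) == 0)
  if (n_empty > 0L)
    warning(sprintf(paste("%d gene(s) have all-zero counts; their log-mean MLE",
                          "is unbounded below and the fitted intercept will",
                          "drift downward -- consider filtering empty genes"),
                    n_empty), call. = FALSE)

  set.seed(seed)
  U <- matrix(stats::rnorm(n * K, sd = 0.1), n, K)
  V <- matrix(stats::rnorm(m * K, sd = 0.1), m, K)
  B <- matrix(0, m, ncol(X), dimnames = list(NULL, colnames(X)))
  G <- matrix(0, n, ncol(Z), dimnames = list(NULL, colnames(Z)))
  if (gene_intercept)
    G[, 1L] <- log((Matrix::rowSums(Y) + 1) / (m + 1))

  model <- new_factor_model(U, V, d = rep(1, K), X = X, B = B, Z = Z, G = G,
                            gene_names = rownames(Y), cell_names = colnames(Y))
  model$init_seed <- as.integer(seed)
  model
}

build_covariates <- function(intercept, extra, nr, what) {
  cols <- list()
  if (intercept)
    cols$`(Intercept)` <- rep(1, nr)
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    storage.mode(extra) <- "double"
    if (nrow(extra) != nr)
      stop_config("%s matrix has %d rows; expected %d", what, nrow(extra), nr)
    if (anyNA(extra) || any(!is.finite(extra)))
      stop_config("%s matrix contains missing or non-finite values", what)
    if (is.null(colnames(extra)))
      colnames(extra) <- paste0("cov", seq_len(ncol(extra)))
    for (k in seq_len(ncol(extra))) cols[[colnames(extra)[k]]] <- extra[, k]
  }
  if (!length(cols)) return(matrix(0, nr, 0L))
  do.call(cbind, cols)
}

# One full pass of cell-side updates: for each cell j independently, run
# `inner_cycles` CCD cycles on the Poisson GLM with response y_.j, design
# [U | X], offset G Z_j', warm-started at (V_j., B_j.).  Cells share no
# mutable state, so the result is identical for any worker count.
update_cells <- function(Y, model, inner_cycles = 4L, workers = 1L,
                         inner_tol = 0, step_cap = 8) {
  K <- model$K; p <- ncol(model$X); q <- ncol(model$Z)
  if (K + p == 0L) return(model)
  D <- cbind(model$U, model$X)
  storage.mode(D) <- "double"
  yp <- Y@p; yi <- Y@i; yx <- Y@x
  n <- model$n
  zero_off <- numeric(n)
  do_col <- function(j) {
    idx <- if (yp[j + 1L] > yp[j]) (yp[j] + 1L):yp[j + 1L] else integer(0)
    off <- if (q > 0L) as.vector(model$G %*% model$Z[j, ]) else zero_off
    beta0 <- c(if (K > 0L) model$V[j, ], if (p > 0L) model$B[j, ])
    res <- ccd_fit_cpp(yi[idx], yx[idx], D, off, beta0,
                       as.integer(inner_cycles), inner_tol, step_cap, 20L, 40)
    c(res$beta, res$n_skipped + res$n_clamped)
  }
  out <- run_over(seq_len(model$m), do_col, workers)
  out <- matrix(unlist(out), nrow = K + p + 1L)
  report_events(out[K + p + 1L, ], "cell")
  if (K > 0L) model$V <- t(out[seq_len(K), , drop = FALSE])
  if (p > 0L) model$B <- t(out[K + seq_len(p), , drop = FALSE])
  colnames(model$B) <- colnames(model$X)
  model
}

# Mirror image of update_cells: for each gene i, response y_i., design
# [V | Z], offset X_i. B', updating (U_i., G_i.).  `Yt` is the transposed
# counts, computed once per fit.
update_genes <- function(Y, model, inner_cycles = 4L, workers = 1L,
                         inner_tol = 0, step_cap = 8, Yt = NULL) {
  K <- model$K; p <- ncol(model$X); q <- ncol(model$Z)
  if (K + q == 0L) return(model)
  if (is.null(Yt)) Yt <- Matrix::t(Y)
  D <- cbind(model$V, model$Z)
  storage.mode(D) <- "double"
  yp <- Yt@p; yi <- Yt@i; yx <- Yt@x
  zero_off <- numeric(model$m)
  do_row <- function(i) {
    idx <- if (yp[i + 1L] > yp[i]) (yp[i] + 1L):yp[i + 1L] else integer(0)
    off <- if (p > 0L) as.vector(model$B %*% model$X[i, ]) else zero_off
    beta0 <- c(if (K > 0L) model$U[i, ], if (q > 0L) model$G[i, ])
    res <- ccd_fit_cpp(yi[idx], yx[idx], D, off, beta0,
                       as.integer(inner_cycles), inner_tol, step_cap, 20L, 40)
    c(res$beta, res$n_skipped + res$n_clamped)
  }
  out <- run_over(seq_len(model$n), do_row, workers)
  out <- matrix(unlist(out), nrow = K + q + 1L)
  report_events(out[K + q + 1L, ], "gene")
  if (K > 0L) model$U <- t(out[seq_len(K), , drop = FALSE])
  if (q > 0L) model$G <- t(out[K + seq_len(q), , drop = FALSE])
  colnames(model$G) <- colnames(model$Z)
  model
}

run_over <- function(idx, f, workers) {
  workers <- max(1L, as.integer(workers))
  if (workers == 1L || .Platform$OS.type == "windows")
    lapply(idx, f)
  else
    parallel::mclapply(idx, f, mc.cores = workers, mc.preschedule = TRUE)
}

report_events <- function(events, side) {
  bad <- which(events > 0)
  if (length(bad))
    warning(sprintf("CCD safeguards triggered for %d %s(s) (first: %s %d)",
                    length(bad), side, side, bad[1L]), call. = FALSE)
  invisible(NULL)
}

#' Orthogonalize the factors of a model
#'
#' Replaces (U, d, V) by the compact SVD of U diag(d) V', computed without
#' forming the n-by-m product: QR-factorize U and V, then take the SVD of
#' the K-by-K product of triangular factors.  The result has orthonormal
#' U and V, non-negative d sorted non-increasing, and preserves
#' U diag(d) V' to machine precision.  Covariate terms are untouched.  The
#' sign of each component is fixed by making the largest-magnitude entry of
#' each U column positive.
#'
#' @param model A `poispca_model` or fitted `poispca` object.
#' @return The model with orthonormalized factors and meaningful scales d.
#' @export
orthogonalize <- function(model) {
  model <- as_factor_model(model)
  K <- model$K
  if (K == 0L) {
    model$d <- numeric(0)
    return(model)
  }
  qu <- qr(model$U)
  qv <- qr(model$V)
  M <- qr.R(qu) %*% (model$d * t(qr.R(qv)))
  sv <- svd(M)
  U <- qr.Q(qu) %*% sv$u
  V <- qr.Q(qv) %*% sv$v
  for (k in seq_len(K)) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  model$U <- U
  model$V <- V
  model$d <- sv$d
  model
}

# fold the scales back into the factors (sqrt(d) each side) so the
# optimizer works with d = 1; exact-H-preserving
fold_d <- function(model) {
  K <- model$K
  if (K == 0L) {
    model$d <- numeric(0)
    return(model)
  }
  if (all(model$d == 1)) return(model)
  s <- sqrt(model$d)
  model$U <- sweep(model$U, 2L, s, `*`)
  model$V <- sweep(model$V, 2L, s, `*`)
  model$d <- rep(1, K)
  model
}

max_abs_change <- function(a, b) {
  pieces <- c(abs(a$U - b$U), abs(a$V - b$V), abs(a$B - b$B), abs(a$G - b$G))
  if (!length(pieces)) 0 else max(pieces)
}

#' Fit a Poisson GLM-PCA model by alternating Poisson regression
#'
#' The model fitting phase.  Each outer iteration runs one full pass of
#' independent cell-wise Poisson GLM updates, one full pass of gene-wise
#' updates, then re-orthogonalizes the factors; every coordinate update is
#' safeguarded, so the log-likelihood is non-decreasing across iterations.
#' Fitting stops when the per-iteration log-likelihood improvement falls
#' below `tol` or after `max_iters` iterations.  Passing a previous fit as
#' `model` resumes it (warm start, trace continued).
#'
#' @inheritParams log_likelihood
#' @param model An initialized [poispca_init()] model, or a previous
#'   `poispca` fit to resume.
#' @param max_iters Maximum number of outer iterations.
#' @param tol Stop when the log-likelihood improves by less than this
#'   (default 1e-4).  `Inf` performs no iterations.
#' @param inner_cycles CCD cycles per Poisson GLM per outer iteration
#'   (default 4; inner fits are inexact — the outer loop revisits them).
#' @param workers Number of worker processes for the independent per-cell /
#'   per-gene fits; results are identical for any worker count.
#' @param orthogonalize_every Re-orthogonalize the factors every this many
#'   iterations (default 1).
#' @param verbose Print one progress line per outer iteration.
#' @return An object of class `poispca`: a list with the orthogonalized
#'   `model`, the fit `trace` (a tibble with one row per iteration:
#'   `iteration`, `loglik`, `elapsed_seconds`, `max_coef_change`), the final
#'   `loglik`, and a `converged` flag.
#' @export
poispca_fit <- function(Y, model, max_iters = 100L, tol = 1e-4,
                        inner_cycles = 4L, workers = 1L, block_width = 128L,
                        orthogonalize_every = 1L, verbose = FALSE) {
  Y <- as_count_matrix(Y)
  prev <- NULL
  if (inherits(model, "poispca")) {
    prev <- model
    model <- model$model
  }
  check_dims(Y, model)
  max_iters <- as.integer(max_iters)
  if (max_iters < 1L) stop_config("max_iters must be >= 1")
  if (!(tol > 0)) stop_config("tol must be positive")
  if (as.integer(inner_cycles) < 1L) stop_config("inner_cycles must be >= 1")

  Yt <- Matrix::t(Y)
  work <- fold_d(model)
  ll_prev <- log_likelihood(Y, work, block_width = block_width)
  if (!is.null(prev)) {
    trace <- prev$trace
    it0 <- max(trace$iteration)
  } else {
    trace <- tibble::tibble(iteration = 0L, loglik = ll_prev,
                            elapsed_seconds = 0, max_coef_change = NA_real_)
    it0 <- 0L
  }

  converged <- !is.finite(tol)
  n_done <- 0L
  if (is.finite(tol)) {
    for (it in seq_len(max_iters)) {
      t0 <- proc.time()[["elapsed"]]
      old <- work
      work <- update_cells(Y, work, inner_cycles = inner_cycles,
                           workers = workers)
      work <- update_genes(Y, work, inner_cycles = inner_cycles,
                           workers = workers, Yt = Yt)
      mc <- max_abs_change(old, work)
      if (it %% orthogonalize_every == 0L)
        work <- fold_d(orthogonalize(work))
      ll <- log_likelihood(Y, work, block_width = block_width)
      elapsed <- proc.time()[["elapsed"]] - t0
      trace <- tibble::add_row(trace, iteration = it0 + it, loglik = ll,
                               elapsed_seconds = elapsed,
                               max_coef_change = mc)
      if (verbose)
        message(sprintf("iter %4d  loglik %.8e  delta %+.3e  (%.2fs)",
                        it0 + it, ll, ll - ll_prev, elapsed))
      n_done <- it
      improvement <- ll - ll_prev
      ll_prev <- ll
      if (improvement < tol) {
        converged <- TRUE
        break
      }
    }
  }

  final <- if (n_done == 0L && !is.null(prev)) prev$model
           else orthogonalize(work)
  structure(list(model = final, trace = trace, loglik = ll_prev,
                 converged = converged, niter = it0 + n_done),
            class = "poispca")
}

#' Fit Poisson GLM-PCA in one call
#'
#' Convenience wrapper: [poispca_init()] followed by [poispca_fit()].
#'
#' @inheritParams poispca_init
#' @inheritParams poispca_fit
#' @param ... Passed on to [poispca_fit()].
#' @return A fitted `poispca` object.
#' @export
poispca <- function(Y, K, gene_covariates = NULL, cell_covariates = NULL,
                    gene_intercept = TRUE, cell_intercept = TRUE,
                    seed = 1L, ...) {
  Y <- as_count_matrix(Y)
  model <- poispca_init(Y, K, gene_covariates = gene_covariates,
                        cell_covariates = cell_covariates,
                        gene_intercept = gene_intercept,
                        cell_intercept = cell_intercept, seed = seed)
  poispca_fit(Y, model, ...)
}
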
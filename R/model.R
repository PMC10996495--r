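#' @title The Poisson GLM-PCA factor model
#'
#' @description A `poispca_model` represents the Poisson GLM-PCA model for an
#' n-genes by m-cells count matrix Y:
#'
#'   y_ij ~ Poisson(exp(h_ij)),
#'   h_ij = sum_k U_ik d_k V_jk + sum_a X_ia B_ja + sum_b G_ib Z_jb
#'
#' where U (n x K) and V (m x K) are the gene and cell factors, d the
#' non-negative scales (all ones during fitting; meaningful after
#' orthogonalization), X (n x p) known gene-level covariates with estimated
#' per-cell coefficients B (m x p), and Z (m x q) known cell-level covariates
#' with estimated per-gene coefficients G (n x q).  The defaults X = 1 and
#' Z = 1 give per-cell intercepts (size factors) in B and per-gene intercepts
#' (baseline expression) in G.
#'
#' @name poispca_model
NULL

new_factor_model <- function(U, V, d, X, B, Z, G,
                             gene_names = NULL, cell_names = NULL) {
  n <- nrow(U); m <- nrow(V); K <- ncol(U)
  stopifnot(ncol(V) == K, length(d) == K,
            nrow(X) == n, nrow(B) == m, ncol(X) == ncol(B),
            nrow(Z) == m, nrow(G) == n, ncol(Z) == ncol(G))
  structure(list(U = U, V = V, d = as.double(d), X = X, B = B, Z = Z, G = G,
                 n = n, m = m, K = K,
                 gene_names = gene_names, cell_names = cell_names),
            class = "poispca_model")
}

as_factor_model <- function(model) {
  if (inherits(model, "poispca")) model$model else model
}

check_dims <- function(Y, model) {
  model <- as_factor_model(model)
  if (nrow(Y) != model$n || ncol(Y) != model$m)
    stop_config("dimension mismatch: counts are %d x %d but model is %d x %d",
                nrow(Y), ncol(Y), model$n, model$m)
  invisible(model)
}

#' Linear predictor for one cell
#'
#' Computes the column h_.j of the log-mean matrix H for a single cell,
#' in O(nK + np + nq) time and O(n) extra memory.
#'
#' @param model A `poispca_model` (or a fitted `poispca` object).
#' @param j Cell index, 1-based.
#' @return Numeric vector of length `n_genes`: the log Poisson means for
#'   every gene in cell `j`.
#' @export
predict_column <- function(model, j) {
  model <- as_factor_model(model)
  if (length(j) != 1L || !is.finite(j) || j < 1L || j > model$m)
    stop_config("cell index %s out of range [1, %d]", format(j), model$m)
  j <- as.integer(j)
  h <- numeric(model$n)
  if (model$K > 0L)
    h <- h + as.vector(model$U %*% (model$d * model$V[j, ]))
  if (ncol(model$X) > 0L)
    h <- h + as.vector(model$X %*% model$B[j, ])
  if (ncol(model$Z) > 0L)
    h <- h + as.vector(model$G %*% model$Z[j, ])
  h
}

# H columns for a block of cells (n x length(cols)); the only place dense
# slabs of H are formed, and callers keep length(cols) <= block_width
predict_block <- function(model, cols) {
  w <- length(cols)
  H <- matrix(0, model$n, w)
  if (model$K > 0L)
    H <- H + model$U %*% (model$d * t(model$V[cols, , drop = FALSE]))
  if (ncol(model$X) > 0L)
    H <- H + model$X %*% t(model$B[cols, , drop = FALSE])
  if (ncol(model$Z) > 0L)
    H <- H + model$G %*% t(model$Z[cols, , drop = FALSE])
  H
}

#' Poisson log-likelihood of a count matrix under a factor model
#'
#' Evaluates the Poisson log-likelihood
#' \deqn{\ell = \sum_{ij} [y_{ij} h_{ij} - \exp(h_{ij})] - \sum_{ij} \log y_{ij}!}
#' where the first sum runs only over stored nonzeros of `Y` and the
#' \eqn{\exp}-sum is accumulated over column blocks of width `block_width`,
#' so peak extra memory is O(n_genes * block_width) and never O(n m).
#'
#' @inheritParams predict_column
#' @param Y A count matrix ([as_count_matrix()]).
#' @param include_constant Include the \eqn{-\sum \log y!} constant so the
#'   value is a true Poisson log-likelihood (default `TRUE`).
#' @param block_width Number of columns per block (default 128).
#' @return The scalar log-likelihood.
#' @export
log_likelihood <- function(Y, model, include_constant = TRUE,
                           block_width = 128L) {
  sum(per_cell_loglik(Y, model, include_constant = include_constant,
                      block_width = block_width))
}

#' Per-cell Poisson log-likelihood
#'
#' Element j is cell j's contribution to [log_likelihood()]; the vector
#' sums to the total.  Useful as a per-cell fit diagnostic.
#'
#' @inheritParams log_likelihood
#' @return Numeric vector of length `n_cells`.
#' @export
per_cell_loglik <- function(Y, model, include_constant = TRUE,
                            block_width = 128L) {
  model <- check_dims(Y, model)
  Y <- as_count_matrix(Y)
  m <- ncol(Y)
  block_width <- max(1L, as.integer(block_width))
  ll <- numeric(m)
  yp <- Y@p; yi <- Y@i; yx <- Y@x
  for (a in seq(1L, m, by = block_width)) {
    cols <- a:min(a + block_width - 1L, m)
    H <- predict_block(model, cols)
    if (!all(is.finite(H))) {
      bad <- cols[which(!apply(is.finite(H), 2L, all))[1L]]
      stop_numeric("non-finite linear predictor in cell %d", bad)
    }
    ll[cols] <- -colSums(exp(H))
    for (jj in seq_along(cols)) {
      j <- cols[jj]
      idx <- if (yp[j + 1L] > yp[j]) (yp[j] + 1L):yp[j + 1L] else integer(0)
      if (length(idx)) {
        yv <- yx[idx]
        hv <- H[yi[idx] + 1L, jj]
        ll[j] <- ll[j] + sum(yv * hv) -
          if (include_constant) sum(lgamma(yv + 1)) else 0
      }
    }
  }
  ll
}
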
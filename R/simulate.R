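#' Simulate single-cell-like counts with known low-rank truth
#'
#' Draws a sparse genes-by-cells count matrix from the exact Poisson
#' GLM-PCA generative model: per-gene baseline log-means uniform on
#' `gene_mean_log_range`, per-cell log size factors normal(0,
#' `cell_size_log_sd`), rank-K factor entries normal(0, `factor_sd`), and
#' `y_ij ~ Poisson(exp(h_ij))`.  The defaults emulate scRNA-seq marginals:
#' most genes have sub-1 mean expression, so the zero fraction is high
#' (above 0.7 at n = 1000, m = 500), and the low-rank heterogeneity makes
#' the pooled marginals look overdispersed even though every entry is
#' Poisson.  Counts are drawn column by column with per-column seeds
#' derived from `seed`, so the draw is reproducible and column order
#' independent; memory stays O(n) beyond the stored nonzeros.
#'
#' @param n,m Number of genes and cells.
#' @param K Rank of the latent structure (0 for intercepts only).
#' @param seed Master seed; the draw is a deterministic function of it.
#' @param gene_mean_log_range Range (log scale) of per-gene baseline
#'   means; default `log(c(0.01, 3))`.
#' @param cell_size_log_sd Standard deviation of per-cell log size
#'   factors; default 0.3.
#' @param factor_sd Standard deviation of latent factor entries; default
#'   0.5.
#' @return A `poispca_sim` object: list with the ground-truth `model`
#'   (a [poispca_model]), the drawn counts `Y` (sparse dgCMatrix), and the
#'   `seed`.
#' @export
simulate_counts <- function(n, m, K, seed = 1L,
                            gene_mean_log_range = log(c(0.01, 3)),
                            cell_size_log_sd = 0.3, factor_sd = 0.5) {
  stopifnot(n >= 1L, m >= 1L, K >= 0L, length(gene_mean_log_range) == 2L,
            cell_size_log_sd >= 0, factor_sd >= 0)
  set.seed(as.integer(seed))
  g0 <- stats::runif(n, gene_mean_log_range[1L], gene_mean_log_range[2L])
  c0 <- stats::rnorm(m, 0, cell_size_log_sd)
  U <- matrix(stats::rnorm(n * K, 0, factor_sd), n, K)
  V <- matrix(stats::rnorm(m * K, 0, factor_sd), m, K)
  gene_names <- sprintf("gene%0*d", nchar(n), seq_len(n))
  cell_names <- sprintf("cell%0*d", nchar(m), seq_len(m))
  model <- new_factor_model(
    U, V, d = rep(1, K),
    X = matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)")),
    B = matrix(c0, m, 1L, dimnames = list(NULL, "(Intercept)")),
    Z = matrix(1, m, 1L, dimnames = list(NULL, "(Intercept)")),
    G = matrix(g0, n, 1L, dimnames = list(NULL, "(Intercept)")),
    gene_names = gene_names, cell_names = cell_names)

  ti <- tj <- tx <- vector("list", m)
  for (j in seq_len(m)) {
    h <- predict_column(model, j)
    if (max(h) > 30)
      stop_config("simulation parameters give log-mean %.1f > 30 in cell %d; reduce ranges",
                  max(h), j)
    set.seed(column_seed(seed, j))
    y <- stats::rpois(n, exp(h))
    nz <- which(y > 0L)
    ti[[j]] <- nz
    tj[[j]] <- rep.int(j, length(nz))
    tx[[j]] <- as.double(y[nz])
  }
  Y <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(n, m),
                            dimnames = list(gene_names, cell_names))
  structure(list(model = model, Y = as_count_matrix(Y),
                 seed = as.integer(seed)),
            class = "poispca_sim")
}

# per-column seed below 2^31, deterministic in (seed, j)
column_seed <- function(seed, j) {
  as.integer(((as.double(seed) %% 46337) * 46337 + j) %% 2147483647)
}

#' Agreement between a fitted model and simulation truth
#'
#' Pearson correlation between the vectorized true and fitted log-mean
#' matrices H (low-rank plus covariate terms), a scale-free measure of
#' parameter recovery in \[-1, 1\].
#'
#' @param truth A `poispca_sim` object (or any `poispca_model`).
#' @param fitted A fitted `poispca` object or `poispca_model`.
#' @param block_width Columns per block when materializing H.
#' @return Scalar correlation.
#' @export
recovery_score <- function(truth, fitted, block_width = 128L) {
  tm <- if (inherits(truth, "poispca_sim")) truth$model else as_factor_model(truth)
  fm <- as_factor_model(fitted)
  if (tm$n != fm$n || tm$m != fm$m)
    stop_config("dimension mismatch between truth (%d x %d) and fit (%d x %d)",
                tm$n, tm$m, fm$n, fm$m)
  ht <- dense_h(tm, block_width)
  hf <- dense_h(fm, block_width)
  if (stats::sd(ht) == 0 || stats::sd(hf) == 0)
    stop_numeric("recovery score undefined: a log-mean matrix has zero variance")
  stats::cor(ht, hf)
}

dense_h <- function(model, block_width = 128L) {
  m <- model$m
  out <- numeric(model$n * m)
  for (a in seq(1L, m, by = block_width)) {
    cols <- a:min(a + block_width - 1L, m)
    out[(cols[1L] - 1L) * model$n + seq_len(model$n * length(cols))] <-
      predict_block(model, cols)
  }
  out
}

#' @exportS3Method base::print
print.poispca_sim <- function(x, ...) {
  cat(sprintf("Simulated Poisson GLM-PCA data: %d genes x %d cells, K = %d, seed = %d\n",
              x$model$n, x$model$m, x$model$K, x$seed))
  nnz <- length(x$Y@x)
  cat(sprintf("  nonzeros: %d (%.1f%% zero)\n", nnz,
              100 * (1 - nnz / (x$model$n * x$model$m))))
  invisible(x)
}
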
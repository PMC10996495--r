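#' PCA-like decomposition of a fitted model
#'
#' Returns the orthogonalized triplet (U, d, V) with the deterministic sign
#' convention applied: orthonormal gene loadings U, non-negative scales d
#' sorted non-increasing, orthonormal cell factors V.  The cell scores
#' (the "PCs" to plot) are `V %*% diag(d)`.  Idempotent, and preserves the
#' reconstruction `U diag(d) V'` to machine precision.
#'
#' @param model A fitted `poispca` object or a `poispca_model`.
#' @return A `poispca_model` with orthonormal factors.
#' @export
to_pca <- function(model) {
  orthogonalize(as_factor_model(model))
}

#' Export a model as a TSV bundle
#'
#' Writes the model matrices as diff-able TSV files with full (17
#' significant digit) precision, so a write/read round trip reproduces the
#' model and its log-likelihood exactly:
#' `<prefix>_gene_factors.tsv` (U), `<prefix>_cell_factors.tsv` (V),
#' `<prefix>_d.tsv` (one row of scales), `<prefix>_coefficients_gene.tsv`
#' (G, one row per gene), `<prefix>_coefficients_cell.tsv` (B, one row per
#' cell), and `<prefix>_covariates_gene.tsv` / `<prefix>_covariates_cell.tsv`
#' (the known X and Z).  First columns hold gene/cell names when present.
#'
#' @param model A `poispca_model` or fitted `poispca` object.
#' @param prefix Output path prefix.
#' @return Invisibly, the written file paths.
#' @export
export_factors <- function(model, prefix) {
  model <- as_factor_model(model)
  gn <- model$gene_names %||% sprintf("gene%d", seq_len(model$n))
  cn <- model$cell_names %||% sprintf("cell%d", seq_len(model$m))
  fac_names <- function(k, nc) colnames(k) %||% sprintf("k%d", seq_len(nc))
  paths <- c(
    write_tsv_precise(model$U, paste0(prefix, "_gene_factors.tsv"),
                      "gene", gn, sprintf("k%d", seq_len(model$K))),
    write_tsv_precise(model$V, paste0(prefix, "_cell_factors.tsv"),
                      "cell", cn, sprintf("k%d", seq_len(model$K))),
    write_tsv_precise(matrix(model$d, 1L), paste0(prefix, "_d.tsv"),
                      NULL, NULL, sprintf("d%d", seq_len(model$K))),
    write_tsv_precise(model$G, paste0(prefix, "_coefficients_gene.tsv"),
                      "gene", gn, fac_names(model$G, ncol(model$G))),
    write_tsv_precise(model$B, paste0(prefix, "_coefficients_cell.tsv"),
                      "cell", cn, fac_names(model$B, ncol(model$B))),
    write_tsv_precise(model$X, paste0(prefix, "_covariates_gene.tsv"),
                      "gene", gn, fac_names(model$X, ncol(model$X))),
    write_tsv_precise(model$Z, paste0(prefix, "_covariates_cell.tsv"),
                      "cell", cn, fac_names(model$Z, ncol(model$Z))))
  invisible(paths)
}

#' Load a model from an exported TSV bundle
#'
#' Inverse of [export_factors()]: reads the TSV bundle written under
#' `prefix` and rebuilds the `poispca_model` exactly.
#'
#' @param prefix Path prefix used at export time.
#' @return A `poispca_model`.
#' @export
import_factors <- function(prefix) {
  fu <- read_tsv_precise(paste0(prefix, "_gene_factors.tsv"), "gene")
  fv <- read_tsv_precise(paste0(prefix, "_cell_factors.tsv"), "cell")
  dd <- read_tsv_precise(paste0(prefix, "_d.tsv"), NULL)
  gg <- read_tsv_precise(paste0(prefix, "_coefficients_gene.tsv"), "gene")
  bb <- read_tsv_precise(paste0(prefix, "_coefficients_cell.tsv"), "cell")
  xx <- read_tsv_precise(paste0(prefix, "_covariates_gene.tsv"), "gene")
  zz <- read_tsv_precise(paste0(prefix, "_covariates_cell.tsv"), "cell")
  dimnames(fu$mat) <- dimnames(fv$mat) <- NULL  # factor columns are unnamed in memory
  new_factor_model(U = fu$mat, V = fv$mat, d = as.vector(dd$mat),
                   X = xx$mat, B = bb$mat, Z = zz$mat, G = gg$mat,
                   gene_names = fu$names, cell_names = fv$names)
}

write_tsv_precise <- function(mat, path, name_col, names, col_names) {
  mat <- matrix(as.double(mat), nrow = if (is.null(dim(mat))) 1L else nrow(mat))
  num <- matrix(sprintf("%.17g", mat), nrow = nrow(mat))
  header <- col_names
  rows <- if (ncol(num)) apply(num, 1L, paste, collapse = "\t") else
    character(nrow(num))
  if (!is.null(name_col)) {
    header <- c(name_col, header)
    rows <- if (ncol(num)) paste(names, rows, sep = "\t") else names
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(rows, con)
  invisible(path)
}

read_tsv_precise <- function(path, name_col) {
  if (!file.exists(path))
    stop_format("missing model file: %s", path)
  lines <- readLines(path)
  header <- if (nzchar(lines[1L])) strsplit(lines[1L], "\t")[[1L]]
            else character(0)
  body <- lines[-1L]
  cells <- lapply(body, function(l)
    if (nzchar(l)) strsplit(l, "\t")[[1L]] else character(0))
  nm <- NULL
  has_names <- !is.null(name_col) && length(header) >= 1L &&
    header[1L] == name_col
  if (has_names) {
    nm <- vapply(cells, function(x) x[1L], character(1L))
    cells <- lapply(cells, `[`, -1L)
    header <- header[-1L]
  }
  ncols <- length(header)
  mat <- matrix(if (ncols) as.double(unlist(cells)) else double(0),
                nrow = length(body), ncol = ncols, byrow = TRUE,
                dimnames = list(NULL, if (ncols) header))
  list(mat = mat, names = nm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.poispca_model <- function(x, ...) {
  cat(sprintf("Poisson GLM-PCA model: %d genes x %d cells, K = %d (%d gene, %d cell covariates)\n",
              x$n, x$m, x$K, ncol(x$X), ncol(x$Z)))
  invisible(x)
}

#' @exportS3Method base::print
print.poispca <- function(x, ...) {
  cat(sprintf("Poisson GLM-PCA fit: %d genes x %d cells, K = %d\n",
              x$model$n, x$model$m, x$model$K))
  cat(sprintf("  log-likelihood %.6f after %d outer iteration(s)%s\n",
              x$loglik, x$niter,
              if (x$converged) " (converged)" else ""))
  if (x$model$K > 0L)
    cat("  scales d:", paste(signif(x$model$d, 4L), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a Poisson GLM-PCA fit
#'
#' Broom-style tidier.  `matrix = "cells"` returns one row per cell and
#' component with the cell score `d_k V_jk` (the coordinates to plot);
#' `"genes"` returns gene loadings `U_ik`; `"d"` returns the scales.
#'
#' @param x A fitted `poispca` object.
#' @param matrix One of `"cells"`, `"genes"`, `"d"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.poispca <- function(x, matrix = c("cells", "genes", "d"), ...) {
  matrix <- match.arg(matrix)
  m <- x$model
  K <- m$K
  comp <- seq_len(K)
  switch(matrix,
    cells = tibble::tibble(
      cell = rep(m$cell_names %||% sprintf("cell%d", seq_len(m$m)), K),
      component = rep(comp, each = m$m),
      score = as.vector(sweep(m$V, 2L, m$d, `*`))),
    genes = tibble::tibble(
      gene = rep(m$gene_names %||% sprintf("gene%d", seq_len(m$n)), K),
      component = rep(comp, each = m$n),
      loading = as.vector(m$U)),
    d = tibble::tibble(component = comp, d = m$d))
}

#' Glance at a Poisson GLM-PCA fit
#'
#' One-row summary: dimensions, rank, final log-likelihood, iteration
#' count, convergence flag, and total fitting time.
#'
#' @inheritParams tidy.poispca
#' @return A one-row tibble.
#' @export
glance.poispca <- function(x, ...) {
  tibble::tibble(n_genes = x$model$n, n_cells = x$model$m, K = x$model$K,
                 loglik = x$loglik, iterations = x$niter,
                 converged = x$converged,
                 elapsed_seconds = sum(x$trace$elapsed_seconds))
}

#' Plot cell scores from a fit
#'
#' Scatterplot of two components of the cell scores `V diag(d)`, the
#' GLM-PCA analogue of a PCA scores plot.
#'
#' @param object A fitted `poispca` object.
#' @param dims Length-2 integer vector of components to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.poispca <- function(object, dims = c(1L, 2L), ...) {
  m <- object$model
  stopifnot(length(dims) == 2L, all(dims >= 1L), all(dims <= m$K))
  scores <- sweep(m$V, 2L, m$d, `*`)
  df <- tibble::tibble(x = scores[, dims[1L]], y = scores[, dims[2L]])
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = sprintf("PC %d", dims[1L]),
                  y = sprintf("PC %d", dims[2L])) +
    ggplot2::theme_minimal()
}
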
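#' Canonicalize a count matrix
#'
#' Validates and canonicalizes a genes-by-cells count matrix for GLM-PCA
#' fitting.  The result is a column-compressed sparse matrix
#' ([Matrix::dgCMatrix-class]) in which duplicate triplets have been summed,
#' explicit zeros dropped, and every stored count is a finite non-negative
#' integer.  Column (cell) slices then cost time proportional to the number
#' of nonzeros in the column.
#'
#' @param x A matrix-like object of counts: a base matrix, a sparse
#'   `Matrix`, or a triplet `data.frame` with columns `i`, `j`, `x`.
#' @param gene_names,cell_names Optional character vectors of row and
#'   column names; override any dimnames already on `x`.
#'
#' @return A `dgCMatrix` of non-negative integer counts.
#' @export
as_count_matrix <- function(x, gene_names = NULL, cell_names = NULL) {
  if (is.data.frame(x)) {
    if (!all(c("i", "j", "x") %in% names(x)))
      stop_format("triplet data frame must have columns 'i', 'j', 'x'")
    x <- Matrix::sparseMatrix(i = x$i, j = x$j, x = as.double(x$x),
                              dims = c(max(x$i), max(x$j)))
  }
  if (is.matrix(x)) x <- methods::as(x, "CsparseMatrix")
  if (!methods::is(x, "sparseMatrix"))
    stop_format("cannot interpret input of class '%s' as a count matrix",
                class(x)[1L])
  if (!methods::is(x, "dgCMatrix")) {
    # C-sparse conversion sums any duplicate triplets
    x <- methods::as(methods::as(x, "generalMatrix"), "CsparseMatrix")
    x <- methods::as(x, "dMatrix")
  }
  v <- x@x
  if (anyNA(v) || any(!is.finite(v)))
    stop_format("count matrix contains missing or non-finite values")
  if (any(v < 0))
    stop_format("count matrix contains negative values")
  if (any(v != round(v)))
    stop_format("count matrix contains non-integer values")
  if (any(v == 0)) x <- Matrix::drop0(x)
  if (!is.null(gene_names)) {
    stopifnot(length(gene_names) == nrow(x))
    rownames(x) <- gene_names
  }
  if (!is.null(cell_names)) {
    stopifnot(length(cell_names) == ncol(x))
    colnames(x) <- cell_names
  }
  x
}

#' Read a count matrix from disk
#'
#' Reads either a MatrixMarket coordinate file (`.mtx`, 1-based indices,
#' the format used for 10x Genomics count matrices) or a dense count table
#' (TSV/CSV with a header row; a non-numeric first column is taken as gene
#' names).  Gene and cell names may also be supplied as separate files with
#' one name per line and no header, mirroring the 10x `genes.tsv` /
#' `barcodes.tsv` convention.
#'
#' @param path Path to the matrix file.
#' @param gene_names_path,cell_names_path Optional paths to name files.
#' @return A canonical count matrix (see [as_count_matrix()]).
#' @export
read_counts <- function(path, gene_names_path = NULL, cell_names_path = NULL) {
  if (!file.exists(path))
    stop_format("counts file not found: %s", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Y <- read_counts_mtx(path)
  } else {
    Y <- read_counts_dense(path)
  }
  gn <- if (!is.null(gene_names_path)) read_name_file(gene_names_path, nrow(Y))
  cn <- if (!is.null(cell_names_path)) read_name_file(cell_names_path, ncol(Y))
  as_count_matrix(Y, gene_names = gn, cell_names = cn)
}

read_counts_mtx <- function(path) {
  m <- tryCatch(Matrix::readMM(path),
                error = function(e) stop_format("malformed MatrixMarket file %s: %s",
                                                path, conditionMessage(e)))
  # locate offending data lines for clear errors; triplets are stored in
  # file order in the T-sparse representation
  if (methods::is(m, "TsparseMatrix")) {
    v <- if (methods::is(m, "nMatrix")) rep(1, length(m@i)) else m@x
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad)) {
      hdr <- n_mtx_header_lines(path)
      stop_format("invalid count at line %d of %s (value %s)",
                  hdr + bad[1L], path, format(v[bad[1L]]))
    }
  }
  m
}

n_mtx_header_lines <- function(path) {
  head <- readLines(path, n = 100L)
  n_comment <- match(FALSE, grepl("^%", head)) - 1L
  n_comment + 1L  # comments plus the dimensions line
}

read_counts_dense <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(utils::read.table(path, header = TRUE, sep = sep,
                                   check.names = FALSE,
                                   stringsAsFactors = FALSE),
                 error = function(e) stop_format("cannot parse %s: %s", path,
                                                 conditionMessage(e)))
  gn <- NULL
  if (ncol(df) >= 1L && !is.numeric(df[[1L]])) {
    gn <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  if (!all(vapply(df, is.numeric, logical(1L))))
    stop_format("non-numeric entries in dense count table %s", path)
  Y <- as.matrix(df)
  rownames(Y) <- gn
  Y
}

read_name_file <- function(path, expected_n) {
  if (!file.exists(path)) stop_format("names file not found: %s", path)
  nm <- readLines(path)
  # 10x genes.tsv files may carry extra tab-separated columns; keep the first
  nm <- vapply(strsplit(nm, "\t", fixed = TRUE), `[[`, character(1L), 1L)
  if (length(nm) != expected_n)
    stop_format("names file %s has %d entries; expected %d",
                path, length(nm), expected_n)
  nm
}

#' Write a count matrix to MatrixMarket format
#'
#' Writes `Y` as a MatrixMarket coordinate integer file (1-based indices)
#' plus optional one-name-per-line TSV files for gene and cell names.
#'
#' @param Y A count matrix (coerced via [as_count_matrix()]).
#' @param path Output `.mtx` path.
#' @param write_names Write `<path>.genes.tsv` / `<path>.cells.tsv` when
#'   `Y` has dimnames.
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(Y, path, write_names = TRUE) {
  Y <- as_count_matrix(Y)
  Matrix::writeMM(Y, path)
  # readMM/writeMM use the "real" field; rewrite header as integer so other
  # MatrixMarket readers treat the file as counts
  lines <- readLines(path)
  lines[1L] <- "%%MatrixMarket matrix coordinate integer general"
  writeLines(lines, path)
  paths <- path
  if (write_names && !is.null(rownames(Y))) {
    p <- paste0(path, ".genes.tsv")
    writeLines(rownames(Y), p)
    paths <- c(paths, p)
  }
  if (write_names && !is.null(colnames(Y))) {
    p <- paste0(path, ".cells.tsv")
    writeLines(colnames(Y), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# error helpers: classed conditions so the CLI can map them to exit codes
stop_format <- function(fmt, ...) {
  stop(structure(class = c("poispca_format_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1L))))
}

stop_config <- function(fmt, ...) {
  stop(structure(class = c("poispca_config_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1L))))
}

stop_numeric <- function(fmt, ...) {
  stop(structure(class = c("poispca_numeric_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1L))))
}
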
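# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom methods is
.as_sparse <- function(x) {
  if (is(x, "dgCMatrix")) return(x)
  if (is(x, "sparseMatrix"))
    return(methods::as(methods::as(x * 1, "generalMatrix"), "CsparseMatrix"))
  methods::as(Matrix::Matrix(as.matrix(x) * 1.0, sparse = TRUE),
              "CsparseMatrix")
}

.check_count_matrix <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must have gene rownames and cell colnames", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers in count matrix", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate cell identifiers in count matrix", call. = FALSE)
  vals <- if (is(counts, "sparseMatrix")) counts@x else counts
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  invisible(TRUE)
}

# Column sums that work for both dense and sparse input.
.colsums <- function(x) {
  if (is(x, "sparseMatrix")) Matrix::colSums(x) else colSums(x)
}

.is_positive_int <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

.stopifnot_positive_int <- function(x, name) {
  if (!.is_positive_int(x))
    stop(sprintf("'%s' must be a single positive integer", name), call. = FALSE)
  invisible(as.integer(x))
}

# Deterministic gene/cell identifier factories.
.gene_ids <- function(n, prefix = "gene") sprintf("%s%05d", prefix, seq_len(n))
.cell_ids <- function(n) sprintf("cell%05d", seq_len(n))

# Fraction of values > 0 per row of a (sparse) matrix over a cell subset.
.frac_detected <- function(mat, cells = NULL) {
  m <- if (is.null(cells)) mat else mat[, cells, drop = FALSE]
  if (is(m, "sparseMatrix")) {
    Matrix::rowSums(m > 0) / ncol(m)
  } else {
    rowSums(m > 0) / ncol(m)
  }
}
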
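#' Write a count matrix as a Matrix Market triplet directory
#'
#' Writes the standard CellRanger-style trio `matrix.mtx`, `barcodes.tsv` and
#' `genes.tsv`, plus an optional `cell_meta.tsv` with per-cell annotations
#' (sample, cluster, time point, lineage, pseudotime, ...).
#'
#' @param counts genes x cells matrix (dense or `dgCMatrix`), with gene
#'   rownames and cell colnames.
#' @param dir output directory, created if missing.
#' @param cell_meta optional data.frame of per-cell metadata; must contain a
#'   `cell` column or have one row per column of `counts` in the same order.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir, cell_meta = NULL) {
  .check_count_matrix(counts)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- .as_sparse(counts)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  if (!is.null(cell_meta)) {
    if (!"cell" %in% names(cell_meta)) {
      stopifnot(nrow(cell_meta) == ncol(counts))
      cell_meta <- cbind(cell = colnames(counts), cell_meta)
    }
    write_tsv(cell_meta, file.path(dir, "cell_meta.tsv"))
  }
  invisible(dir)
}

#' Read a Matrix Market count directory
#'
#' @param dir directory written by [write_counts_mtx()] (or any directory with
#'   `matrix.mtx`, `barcodes.tsv`, `genes.tsv`).
#' @return list with `counts` (dgCMatrix, genes x cells) and `cell_meta`
#'   (data.frame or NULL).
#' @export
read_counts_mtx <- function(dir) {
  counts <- .as_sparse(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  meta_path <- file.path(dir, "cell_meta.tsv")
  cell_meta <- if (file.exists(meta_path)) read_tsv(meta_path) else NULL
  list(counts = counts, cell_meta = cell_meta)
}

#' Read gene sets from a GMT file
#'
#' GMT is tab-delimited: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT", call. = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Minimal TSV I/O used across the package
#'
#' Plain tab-separated tables with a header, no quoting surprises, strings
#' kept as strings.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `path` (write) or a data.frame (read).
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a regulon table (TF, target, weight)
#'
#' @param path TSV with columns `tf`, `target`, `weight`.
#' @return data.frame with those columns.
#' @export
read_regulons <- function(path) {
  df <- read_tsv(path)
  need <- c("tf", "target", "weight")
  if (!all(need %in% names(df)))
    stop("regulon table must have columns tf, target, weight", call. = FALSE)
  df$weight <- as.numeric(df$weight)
  df
}

#' Map gene identifiers through a two-column orthology table
#'
#' Simple join used to convert e.g. human symbols to mouse symbols before
#' signature scoring across species. Genes without a mapping are dropped.
#'
#' @param genes character vector of identifiers.
#' @param table data.frame whose first column matches `genes` and second column
#'   holds the mapped identifier, or a path to such a TSV.
#' @return character vector of mapped identifiers (unmatched genes removed).
#' @export
map_orthologs <- function(genes, table) {
  if (is.character(table) && length(table) == 1L) table <- read_tsv(table)
  stopifnot(ncol(table) >= 2)
  idx <- match(genes, table[[1]])
  out <- table[[2]][idx]
  unique(out[!is.na(out)])
}
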
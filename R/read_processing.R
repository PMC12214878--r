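#' Deconvolute droplet barcodes against a whitelist
#'
#' Assigns each read to a whitelist barcode in three stages with strict
#' precedence: (a) exact match; (b) one-mismatch match, accepted only when
#' exactly one whitelist barcode lies at Hamming distance 1 (an `N` base
#' matches nothing exactly and counts as a mismatch at its position); (c)
#' alignment rescue, in which a still-unmatched read is aligned (Levenshtein
#' edit distance) against the set of barcodes matched in stages (a) and (b)
#' and accepted if a unique barcode is strictly closest within
#' `rescue_max_edit` edits. Any tie at the deciding distance leaves the read
#' unassigned.
#'
#' @param reads data.frame with columns `read_id` and `barcode` (additional
#'   columns are ignored).
#' @param whitelist character vector of equal-length barcodes.
#' @param rescue_max_edit maximum edit distance for the rescue stage.
#' @return data.frame with `read_id`, `assigned_barcode` (NA when
#'   unassigned) and `method` (one of `exact`, `one_mismatch`,
#'   `alignment_rescue`, `unassigned`), one row per input read in input order.
#' @export
deconvolute_barcodes <- function(reads, whitelist, rescue_max_edit = 2) {
  stopifnot(is.data.frame(reads), all(c("read_id", "barcode") %in% names(reads)))
  whitelist <- unique(whitelist)
  bl <- unique(nchar(whitelist))
  if (length(bl) != 1)
    stop("whitelist barcodes must all have the same length", call. = FALSE)
  if (any(nchar(reads$barcode) != bl))
    stop("read barcodes must match the whitelist barcode length", call. = FALSE)

  assigned <- rep(NA_character_, nrow(reads))
  method <- rep("unassigned", nrow(reads))

  # (a) exact
  exact <- match(reads$barcode, whitelist)
  hit <- !is.na(exact)
  assigned[hit] <- whitelist[exact[hit]]
  method[hit] <- "exact"

  # (b) one mismatch, via a variant table of all single-substitution
  # neighbours (including N) of each whitelist barcode; variants reachable
  # from more than one whitelist barcode are ambiguous and dropped.
  todo <- which(!hit)
  if (length(todo) > 0) {
    lookup <- .one_mismatch_table(whitelist, bl)
    m <- lookup$barcode[match(reads$barcode[todo], lookup$variant)]
    ok <- !is.na(m)
    assigned[todo[ok]] <- m[ok]
    method[todo[ok]] <- "one_mismatch"
  }

  # (c) alignment rescue against the observed matched-barcode set
  todo <- which(is.na(assigned))
  matched <- unique(assigned[!is.na(assigned)])
  if (length(todo) > 0 && length(matched) > 0) {
    un_bc <- unique(reads$barcode[todo])
    d <- utils::adist(un_bc, matched)
    best <- apply(d, 1, min)
    n_best <- rowSums(d == best)
    ok <- best <= rescue_max_edit & n_best == 1
    rescue_to <- ifelse(ok, matched[apply(d, 1, which.min)], NA_character_)
    m <- rescue_to[match(reads$barcode[todo], un_bc)]
    hit <- !is.na(m)
    assigned[todo[hit]] <- m[hit]
    method[todo[hit]] <- "alignment_rescue"
  }

  data.frame(read_id = reads$read_id, assigned_barcode = assigned,
             method = method)
}

# variant -> whitelist barcode map for Hamming distance exactly 1;
# ambiguous variants (two whitelist parents) are removed.
.one_mismatch_table <- function(whitelist, len) {
  alphabet <- c("A", "C", "G", "T", "N")
  chars <- do.call(rbind, strsplit(whitelist, ""))
  variants <- character(0)
  parents <- character(0)
  for (pos in seq_len(len)) {
    for (sub in alphabet) {
      keep <- chars[, pos] != sub
      if (!any(keep)) next
      v <- chars[keep, , drop = FALSE]
      v[, pos] <- sub
      variants <- c(variants, apply(v, 1, paste0, collapse = ""))
      parents <- c(parents, whitelist[keep])
    }
  }
  dup <- variants %in% variants[duplicated(variants)]
  # a variant identical to a whitelist barcode is owned by the exact stage
  bad <- dup | variants %in% whitelist
  data.frame(variant = variants[!bad], barcode = parents[!bad])
}

#' Select cell-containing barcodes from a barcode rank plot
#'
#' Reproduces knee-plot cell calling. In manual mode (`override_cutoff`
#' given) every barcode with at least that many reads is selected. In
#' automatic mode the knee is located on the log10(count) versus log10(rank)
#' curve as the rank with the largest perpendicular distance, on the upper
#' (concave) side, from the chord joining the curve's endpoints; all barcodes
#' with counts at or above the knee count are selected.
#'
#' @param counts_per_barcode named numeric vector: reads per barcode.
#' @param override_cutoff optional manual count cutoff.
#' @return character vector of selected barcodes.
#' @export
select_cell_barcodes <- function(counts_per_barcode, override_cutoff = NULL) {
  if (length(counts_per_barcode) == 0) stop("empty barcode counts", call. = FALSE)
  if (is.null(names(counts_per_barcode)))
    stop("counts_per_barcode must be named by barcode", call. = FALSE)
  if (!is.null(override_cutoff)) {
    return(names(counts_per_barcode)[counts_per_barcode >= override_cutoff])
  }
  if (length(counts_per_barcode) < 3)
    stop("automatic knee detection needs at least 3 barcodes", call. = FALSE)
  ord <- order(-counts_per_barcode, names(counts_per_barcode))
  cnt <- counts_per_barcode[ord]
  n <- length(cnt)
  x <- log10(seq_len(n))
  y <- log10(pmax(cnt, 1e-12))
  knee <- knee_rank(x, y)
  threshold <- cnt[knee]
  names(counts_per_barcode)[counts_per_barcode >= threshold]
}

#' Knee rank of a descending log-log barcode curve
#'
#' Signed point-to-chord distance: the chord joins the first and last point;
#' distances are positive on the upper side of the chord (where the knee of a
#' barcode rank curve lies) and the first maximizing index is returned.
#'
#' @param x,y coordinates of the curve (same length, `x` increasing).
#' @return integer index of the knee point.
#' @export
knee_rank <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n)
  dx <- x[n] - x[1]
  dy <- y[n] - y[1]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) return(1L)
  # cross product of (chord) x (point - start); for a descending curve the
  # upper side gives negative raw values, so flip the sign
  d_signed <- -(dy * (x - x[1]) - dx * (y - y[1])) / len
  as.integer(which.max(d_signed))
}

#' Flatten UMIs into a genes x cells count matrix
#'
#' Counts, for every (cell, gene) pair, the number of distinct UMI sequences
#' observed — collapsing PCR duplicates by exact UMI string identity (no UMI
#' error correction).
#'
#' @param reads data.frame with columns `read_id`, `umi`, `gene` and either a
#'   `cell` column or a `barcode` column to use when `assignments` is NULL.
#' @param assignments optional output of [deconvolute_barcodes()]; assigned
#'   barcodes become cell identifiers and unassigned reads are dropped.
#' @param cells optional character vector (e.g. from
#'   [select_cell_barcodes()]); restricts the matrix to these cells.
#' @return dgCMatrix of distinct-UMI counts, genes x cells.
#' @export
flatten_umis <- function(reads, assignments = NULL, cells = NULL) {
  stopifnot(all(c("umi", "gene") %in% names(reads)))
  if (!is.null(assignments)) {
    idx <- match(reads$read_id, assignments$read_id)
    cell <- assignments$assigned_barcode[idx]
  } else {
    cell <- reads$cell %||% reads$barcode
    if (is.null(cell)) stop("no cell or barcode column in reads", call. = FALSE)
  }
  keep <- !is.na(cell)
  if (!is.null(cells)) keep <- keep & cell %in% cells
  df <- unique(data.frame(cell = cell[keep], gene = reads$gene[keep],
                          umi = reads$umi[keep]))
  if (nrow(df) == 0) stop("no assigned reads to count", call. = FALSE)
  gene_levels <- sort(unique(df$gene))
  cell_levels <- if (is.null(cells)) sort(unique(df$cell)) else cells
  Matrix::sparseMatrix(
    i = match(df$gene, gene_levels),
    j = match(df$cell, cell_levels),
    x = 1,
    dims = c(length(gene_levels), length(cell_levels)),
    dimnames = list(gene_levels, cell_levels)
  )
}

#' Poisson coverage-dependent duplicate filter
#'
#' For each genomic unit, the coverage of exactly identical reads
#' (`dup_count`) is compared with the coverage of adjacent sequence
#' (`adjacent_coverage`), taken as the rate of a Poisson model. When the
#' upper-tail probability `P(X >= dup_count)` with `X ~ Poisson(lambda =
#' adjacent_coverage)` falls below `alpha`, the stack is deemed artifactual
#' and its count is reduced to the adjacent coverage (rounded, at least 1);
#' otherwise the observed count is kept. A reduction never increases a count.
#'
#' @param stacks data.frame with columns `unit_id`, `dup_count`,
#'   `adjacent_coverage`.
#' @param alpha tail-probability cutoff (default 0.001).
#' @return input data.frame plus `tail_p`, `flagged` and `reduced_count`.
#' @export
poisson_dedup <- function(stacks, alpha = 0.001) {
  stopifnot(is.data.frame(stacks),
            all(c("unit_id", "dup_count", "adjacent_coverage") %in% names(stacks)))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (any(stacks$dup_count < 0) || any(stacks$adjacent_coverage < 0))
    stop("counts and coverages must be non-negative", call. = FALSE)
  tail_p <- stats::ppois(stacks$dup_count - 1, lambda = stacks$adjacent_coverage,
                         lower.tail = FALSE)
  flagged <- tail_p < alpha
  reduced <- ifelse(flagged,
                    pmin(stacks$dup_count, pmax(1, round(stacks$adjacent_coverage))),
                    stacks$dup_count)
  out <- stacks
  out$tail_p <- tail_p
  out$flagged <- flagged
  out$reduced_count <- reduced
  out
}

#' Estimate adjacent-sequence coverage from a coverage track
#'
#' Helper for preparing [poisson_dedup()] input when only a per-base coverage
#' vector is available: the adjacent coverage of a position is the mean
#' coverage in a window of `window` bases on each side, excluding the
#' position itself.
#'
#' @param coverage numeric per-position coverage track.
#' @param positions integer positions (1-based indices into `coverage`).
#' @param window half-window width in positions.
#' @return numeric vector of adjacent coverages, one per position.
#' @export
estimate_adjacent_coverage <- function(coverage, positions, window = 50) {
  vapply(positions, function(p) {
    lo <- max(1L, p - window)
    hi <- min(length(coverage), p + window)
    idx <- setdiff(lo:hi, p)
    mean(coverage[idx])
  }, numeric(1))
}
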
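.DNA <- c("A", "C", "G", "T")

.random_barcodes <- function(n, len) {
  m <- matrix(sample(.DNA, n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste0, collapse = "")
}

# Pairwise-safe whitelist by rejection sampling: candidates are kept only if
# at Hamming distance >= min_dist from every accepted barcode.
.sample_whitelist <- function(size, len, min_dist, max_tries = 200L * size) {
  accepted <- character(0)
  accepted_mat <- matrix(character(0), nrow = 0, ncol = len)
  tries <- 0L
  while (length(accepted) < size) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("whitelist separation constraint infeasible for given length/size",
           call. = FALSE)
    cand <- paste0(sample(.DNA, len, replace = TRUE), collapse = "")
    cand_chars <- strsplit(cand, "")[[1]]
    if (nrow(accepted_mat) > 0) {
      dists <- rowSums(accepted_mat != matrix(cand_chars, nrow = nrow(accepted_mat),
                                              ncol = len, byrow = TRUE))
      if (min(dists) < min_dist) next
    }
    accepted <- c(accepted, cand)
    accepted_mat <- rbind(accepted_mat, cand_chars)
  }
  accepted
}

.mutate_barcodes <- function(barcodes, rate) {
  if (rate <= 0) return(barcodes)
  chars <- do.call(rbind, strsplit(barcodes, ""))
  hit <- matrix(stats::runif(length(chars)) < rate, nrow = nrow(chars))
  n_hit <- sum(hit)
  if (n_hit > 0) {
    # substitute with one of the three other bases, uniformly
    orig <- chars[hit]
    repl <- vapply(orig, function(b) sample(setdiff(.DNA, b), 1), character(1))
    chars[hit] <- repl
  }
  apply(chars, 1, paste0, collapse = "")
}

#' Simulate droplet sequencing read records with barcode errors
#'
#' Emulates the raw input of droplet (ddSeq-style) barcode deconvolution: a
#' whitelist of mutually well-separated cell barcodes (pairwise Hamming
#' distance at least `min_whitelist_dist`, so one-mismatch matching is
#' well-posed), reads from real cells whose observed barcode is the cell's
#' whitelist barcode with i.i.d. per-base substitutions, and ambient reads
#' carrying random non-whitelist barcodes. UMIs are uniform random strings;
#' gene labels follow a fixed rank-weighted distribution.
#'
#' @param whitelist_size number of whitelist barcodes.
#' @param barcode_length barcode length in bases.
#' @param n_cells number of cell-containing droplets (must not exceed
#'   `whitelist_size`).
#' @param reads_per_cell reads generated per cell.
#' @param substitution_rate per-base substitution probability on cell reads.
#' @param ambient_barcode_rate fraction of all reads that are ambient
#'   (random non-whitelist barcodes).
#' @param seed integer seed.
#' @param min_whitelist_dist minimum pairwise Hamming distance of the whitelist.
#' @param umi_length UMI length in bases.
#' @param n_gene_labels size of the gene-label alphabet.
#' @return list with `reads` (data.frame read_id/barcode/umi/gene),
#'   `whitelist` (character vector) and `truth` (data.frame
#'   read_id/true_barcode/is_ambient; `true_barcode` is NA for ambient reads).
#' @export
simulate_ddseq_reads <- function(whitelist_size = 50, barcode_length = 12,
                                 n_cells = 20, reads_per_cell = 200,
                                 substitution_rate = 0.005,
                                 ambient_barcode_rate = 0.1,
                                 seed = 1L, min_whitelist_dist = 3,
                                 umi_length = 8, n_gene_labels = 100) {
  .stopifnot_positive_int(whitelist_size, "whitelist_size")
  .stopifnot_positive_int(n_cells, "n_cells")
  if (n_cells > whitelist_size)
    stop("n_cells cannot exceed whitelist_size", call. = FALSE)
  if (ambient_barcode_rate < 0 || ambient_barcode_rate >= 1)
    stop("ambient_barcode_rate must be in [0, 1)", call. = FALSE)

  withr::with_seed(seed, {
    whitelist <- .sample_whitelist(whitelist_size, barcode_length,
                                   min_whitelist_dist)
    cell_bc <- whitelist[seq_len(n_cells)]

    n_cell_reads <- n_cells * reads_per_cell
    n_ambient <- round(ambient_barcode_rate / (1 - ambient_barcode_rate) *
                         n_cell_reads)
    true_bc <- rep(cell_bc, each = reads_per_cell)
    obs_bc <- .mutate_barcodes(true_bc, substitution_rate)

    if (n_ambient > 0) {
      amb <- .random_barcodes(2L * n_ambient + 10L, barcode_length)
      amb <- setdiff(amb, whitelist)
      while (length(amb) < n_ambient)
        amb <- setdiff(c(amb, .random_barcodes(n_ambient, barcode_length)),
                       whitelist)
      amb <- amb[seq_len(n_ambient)]
    } else amb <- character(0)

    n_reads <- n_cell_reads + n_ambient
    umis <- .random_barcodes(n_reads, umi_length)
    gene_p <- 1 / seq_len(n_gene_labels)
    genes <- sample(sprintf("g%03d", seq_len(n_gene_labels)), n_reads,
                    replace = TRUE, prob = gene_p / sum(gene_p))

    reads <- data.frame(
      read_id = sprintf("read%07d", seq_len(n_reads)),
      barcode = c(obs_bc, amb),
      umi = umis,
      gene = genes
    )
    truth <- data.frame(
      read_id = reads$read_id,
      true_barcode = c(true_bc, rep(NA_character_, n_ambient)),
      is_ambient = c(rep(FALSE, n_cell_reads), rep(TRUE, n_ambient))
    )
    list(reads = reads, whitelist = whitelist, truth = truth)
  })
}

#' Simulate PCR duplicate stacks with Poisson background
#'
#' Emulates the input of the coverage-dependent duplicate filter: genomic
#' units whose identical-read coverage is Poisson around the coverage of
#' adjacent sequence, plus artifact units whose identical-read count is
#' inflated by `artifact_multiplier`.
#'
#' @param n_positions number of background units.
#' @param background_lambda Poisson rate of background duplication; also the
#'   adjacent-sequence coverage attached to every unit.
#' @param n_artifacts number of artifact units.
#' @param artifact_multiplier inflation factor (> 1) for artifact units.
#' @param seed integer seed.
#' @return data.frame with `unit_id`, `dup_count`, `adjacent_coverage`,
#'   `is_artifact`.
#' @export
simulate_duplicate_stacks <- function(n_positions = 1000, background_lambda = 2,
                                      n_artifacts = 0, artifact_multiplier = 10,
                                      seed = 1L) {
  .stopifnot_positive_int(n_positions, "n_positions")
  if (background_lambda <= 0) stop("background_lambda must be > 0", call. = FALSE)
  if (n_artifacts > 0 && artifact_multiplier <= 1)
    stop("artifact_multiplier must be > 1", call. = FALSE)

  withr::with_seed(seed, {
    bg <- stats::rpois(n_positions, background_lambda)
    art <- if (n_artifacts > 0) {
      ceiling(artifact_multiplier * pmax(1L, stats::rpois(n_artifacts,
                                                          background_lambda)))
    } else integer(0)
    n <- n_positions + n_artifacts
    data.frame(
      unit_id = sprintf("unit%06d", seq_len(n)),
      dup_count = c(bg, art),
      adjacent_coverage = rep(background_lambda, n),
      is_artifact = c(rep(FALSE, n_positions), rep(TRUE, n_artifacts))
    )
  })
}
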
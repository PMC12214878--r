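#' Simulate centered expression driven by planted TF activities
#'
#' Builds a regulon table (TF, target, weight with weights in \{-1, +1\}) and
#' a dense genes x cells expression matrix in which each target gene equals
#' `weight * activity_scale * activity + N(0, noise_sd)` where `activity` is
#' the planted per-cell activity of its TF (standard normal across cells).
#' Background genes carry pure noise. Target sets are disjoint across TFs.
#' `targets_per_tf` may be a vector (recycled across TFs) so that some TFs
#' fall below the downstream minimum-target filter.
#'
#' @param n_tfs number of transcription factors.
#' @param targets_per_tf targets per TF (scalar or vector of length `n_tfs`).
#' @param n_cells number of cells.
#' @param activity_scale signal magnitude; 0 plants no activity signal.
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_background_genes genes with no regulator.
#' @param seed integer seed.
#' @return list with `expr` (dense genes x cells matrix, roughly centered),
#'   `regulons` (data.frame tf/target/weight) and `truth` (list with
#'   `tf_activity`, a TF x cells matrix of planted activities).
#' @export
simulate_regulon_data <- function(n_tfs = 10, targets_per_tf = 30,
                                  n_cells = 200, activity_scale = 1,
                                  noise_sd = 1, n_background_genes = 100,
                                  seed = 1L) {
  .stopifnot_positive_int(n_tfs, "n_tfs")
  .stopifnot_positive_int(n_cells, "n_cells")
  tpt <- rep_len(as.integer(targets_per_tf), n_tfs)
  if (any(tpt < 1)) stop("targets_per_tf must be positive", call. = FALSE)

  withr::with_seed(seed, {
    n_targets <- sum(tpt)
    n_genes <- n_targets + n_background_genes
    genes <- .gene_ids(n_genes)
    cells <- .cell_ids(n_cells)
    tfs <- sprintf("TF%02d", seq_len(n_tfs))

    tf_of_target <- rep(seq_len(n_tfs), times = tpt)
    target_genes <- genes[seq_len(n_targets)]
    weight <- sample(c(-1, 1), n_targets, replace = TRUE)
    regulons <- data.frame(tf = tfs[tf_of_target], target = target_genes,
                           weight = weight)

    activity <- matrix(stats::rnorm(n_tfs * n_cells), nrow = n_tfs,
                       dimnames = list(tfs, cells))
    expr <- matrix(stats::rnorm(n_genes * n_cells, sd = noise_sd),
                   nrow = n_genes, dimnames = list(genes, cells))
    expr[seq_len(n_targets), ] <- expr[seq_len(n_targets), ] +
      weight * activity_scale * activity[tf_of_target, , drop = FALSE]

    list(expr = expr, regulons = regulons,
         truth = list(tf_activity = activity))
  })
}
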
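#' Default configuration of the demo pipeline
#'
#' Returns the full configuration list consumed by [run_pipeline()], with the
#' pipeline's standard thresholds (QC, marker criteria, correlation
#' selection) and simulation settings sized so the whole demonstration runs
#' in minutes on one CPU.
#'
#' @return named list of configuration entries.
#' @export
default_pipeline_config <- function() {
  list(
    simulation = list(
      n_cells = 600, n_genes = 1500, n_lineages = 2, n_dynamic_genes = 40,
      program_log2fc = 2, nb_dispersion = 0.3, libsize_sigma = 0.3,
      mito_fraction_range = c(0.01, 0.08)
    ),
    qc = list(min_genes = 200, max_mito_pct = 10),
    hvg = list(n = 1000),
    pca = list(n_pcs = 30, delta = 0.1, min_pcs = 2),
    clustering = list(resolution = 0.6, n_neighbors = 20),
    degs = list(min_pct = 0.25, min_fc = 1.5, alpha = 0.05),
    trajectory = list(pseudotime_cutoff = 1, min_frac = 0.10,
                      alpha = 0.05, min_r = 0.25),
    gsea = list(n_perm = 500, min_set_size = 5),
    seed = 1L
  )
}

#' Run the full demonstration pipeline from one configuration
#'
#' Simulates a trajectory dataset with planted lineage programs, then runs
#' the complete analysis chain: QC filtering, log-normalization, variable
#' gene selection, scaling, PCA with the component-count rule, SNN/Louvain
#' clustering, signature Z-scoring of the planted programs, cluster-vs-rest
#' marker calling, per-lineage pseudotime correlation with selection, and
#' pre-ranked GSEA of the correlation-ranked genes against the planted gene
#' sets. Everything is seeded; the same configuration yields bit-identical
#' results.
#'
#' @param config a configuration list (see [default_pipeline_config()]) or
#'   the path of a YAML file holding one; missing entries fall back to the
#'   defaults.
#' @param seed overrides `config$seed` when given.
#' @return list with the intermediate and final products: `sim`, `counts`
#'   (QC-passing), `norm`, `hvgs`, `pca`, `n_pcs`, `clusters`, `ari`,
#'   `signature_scores`, `degs`, `correlations`, `selected`, `gsea`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (!is.null(seed)) cfg$seed <- seed

  sim_cfg <- sim_config(
    n_cells = cfg$simulation$n_cells, n_genes = cfg$simulation$n_genes,
    n_subpopulations = cfg$simulation$n_lineages,
    program_log2fc = cfg$simulation$program_log2fc,
    nb_dispersion = cfg$simulation$nb_dispersion,
    libsize_sigma = cfg$simulation$libsize_sigma,
    mito_fraction_range = unlist(cfg$simulation$mito_fraction_range),
    seed = cfg$seed
  )
  sim <- simulate_trajectory_counts(sim_cfg,
                                    n_lineages = cfg$simulation$n_lineages,
                                    n_dynamic_genes = cfg$simulation$n_dynamic_genes)

  counts <- qc_filter(sim$counts, min_genes = cfg$qc$min_genes,
                      max_mito_pct = cfg$qc$max_mito_pct)
  norm <- log_normalize(counts)
  hvgs <- select_hvgs(counts, n = min(cfg$hvg$n, nrow(counts)))
  scaled <- scale_rows(as.matrix(norm[hvgs, , drop = FALSE]))
  pca <- run_pca(scaled, n_pcs = cfg$pca$n_pcs)
  n_pcs <- max(select_pcs(pca, delta = cfg$pca$delta,
                          min_pcs = cfg$pca$min_pcs), 2L)
  clusters <- cluster_cells(pca$embeddings[, seq_len(n_pcs), drop = FALSE],
                            resolution = cfg$clustering$resolution,
                            n_neighbors = cfg$clustering$n_neighbors,
                            seed = cfg$seed)
  truth_labels <- sim$truth$lineage_true[colnames(counts)]
  ari <- adjusted_rand_index(clusters, truth_labels)

  sig_scores <- signature_zscore(norm, sim$truth$dynamic_genes,
                                 cluster_labels = clusters)

  # markers of the most differentiated cluster (highest mean pseudotime),
  # where the planted dynamic programs are up-regulated
  pt_by_cluster <- tapply(sim$cell_meta$pseudotime[
    match(names(clusters), sim$cell_meta$cell)], clusters, mean)
  late_cluster <- as.integer(names(which.max(pt_by_cluster)))
  in_late <- names(clusters)[clusters == late_cluster]
  degs <- call_degs(norm, in_late, setdiff(colnames(norm), in_late),
                    min_pct = cfg$degs$min_pct, min_fc = cfg$degs$min_fc,
                    alpha = cfg$degs$alpha)

  lin <- sim$cell_meta[sim$cell_meta$cell %in% colnames(counts),
                       c("cell", "lineage", "pseudotime", "time_point")]
  lin <- apply_pseudotime_cutoff(lin, cfg$trajectory$pseudotime_cutoff)
  lineages <- sort(unique(lin$lineage))
  correlations <- lapply(lineages, function(l)
    correlate_features(norm, lin, min_frac = cfg$trajectory$min_frac,
                       lineage = l))
  names(correlations) <- lineages
  selected <- lapply(correlations, select_and_rank,
                     alpha = cfg$trajectory$alpha, min_r = cfg$trajectory$min_r)

  # enrichment runs on the full tested ranking so set membership is
  # informative; `selected` holds the significant-only ranked list
  gsea <- lapply(lineages, function(l) {
    tab <- correlations[[l]]
    tab <- tab[tab$tested, , drop = FALSE]
    if (nrow(tab) == 0) return(NULL)
    stats_vec <- stats::setNames(tab$r, tab$feature)
    preranked_gsea(stats_vec, sim$truth$dynamic_genes,
                   n_perm = cfg$gsea$n_perm, seed = cfg$seed,
                   min_set_size = cfg$gsea$min_set_size)
  })
  names(gsea) <- lineages

  list(config = cfg, sim = sim, counts = counts, norm = norm, hvgs = hvgs,
       pca = pca, n_pcs = n_pcs, clusters = clusters, ari = ari,
       signature_scores = sig_scores, degs = degs,
       correlations = correlations, selected = selected, gsea = gsea)
}
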
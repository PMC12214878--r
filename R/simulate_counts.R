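# Negative-binomial draw with variance mu + mu^2 * phi; phi = 0 is Poisson.
.rnb <- function(n, mu, phi) {
  if (phi <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

# Shared machinery: given per-cell expected means for non-mito genes, add a
# mitochondrial block sized so each cell's expected mito UMI fraction hits a
# uniform draw from cfg$mito_fraction_range, then sample NB counts.
.sample_counts <- function(cfg, mu_nonmito) {
  n_mito <- cfg$n_mito_genes
  n_cells <- cfg$n_cells
  f <- stats::runif(n_cells, cfg$mito_fraction_range[1], cfg$mito_fraction_range[2])
  nonmito_total <- colSums(mu_nonmito)
  mito_total <- f / (1 - f) * nonmito_total
  mu_mito <- matrix(rep(mito_total / n_mito, each = n_mito), nrow = n_mito)
  mu <- rbind(mu_mito, mu_nonmito)
  counts <- matrix(.rnb(length(mu), as.vector(mu), cfg$nb_dispersion),
                   nrow = nrow(mu))
  rownames(counts) <- c(.gene_ids(n_mito, "mt-gene"),
                        .gene_ids(cfg$n_genes - n_mito))
  colnames(counts) <- .cell_ids(n_cells)
  .as_sparse(counts)
}

.base_gene_means <- function(cfg) {
  stats::rlnorm(cfg$n_genes - cfg$n_mito_genes,
                meanlog = cfg$gene_mean_meanlog, sdlog = cfg$gene_mean_sdlog)
}

#' Simulate UMI counts with planted subpopulation programs
#'
#' Draws a genes x cells negative-binomial UMI count matrix with log-normal
#' per-cell library-size factors and a mitochondrial gene block (genes named
#' `mt-*`) producing per-cell mitochondrial fractions inside
#' `cfg$mito_fraction_range`. Each of the `cfg$n_subpopulations`
#' subpopulations receives a disjoint program of `cfg$program_size` genes
#' whose expected expression is multiplied by `2^cfg$program_log2fc` in that
#' subpopulation only. Identical `cfg` (including seed) gives bit-identical
#' output.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (dgCMatrix genes x cells), `cell_meta`
#'   (data.frame: cell, sample, subpopulation), `gene_meta` (data.frame:
#'   gene, is_mito) and `truth` (list: `cell_labels` named integer vector,
#'   `program_genes` list of per-subpopulation gene vectors).
#' @export
simulate_subpopulation_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n_prog_genes <- cfg$program_size * cfg$n_subpopulations
    base_mean <- .base_gene_means(cfg)
    nonmito_ids <- .gene_ids(cfg$n_genes - cfg$n_mito_genes)
    prog_idx <- sample(length(nonmito_ids), n_prog_genes)
    program_genes <- split(nonmito_ids[prog_idx],
                           rep(seq_len(cfg$n_subpopulations), each = cfg$program_size))
    names(program_genes) <- paste0("subpop", seq_len(cfg$n_subpopulations))
    prog_of_gene <- integer(length(nonmito_ids))          # 0 = no program
    prog_of_gene[prog_idx] <- rep(seq_len(cfg$n_subpopulations),
                                  each = cfg$program_size)

    labels <- sample(rep_len(seq_len(cfg$n_subpopulations), cfg$n_cells))
    libsize <- stats::rlnorm(cfg$n_cells, 0, cfg$libsize_sigma)

    mu <- outer(base_mean, libsize)
    fc <- 2^cfg$program_log2fc
    for (s in seq_len(cfg$n_subpopulations)) {
      rows <- prog_of_gene == s
      cols <- labels == s
      mu[rows, cols] <- mu[rows, cols] * fc
    }
    counts <- .sample_counts(cfg, mu)

    labels_named <- stats::setNames(labels, colnames(counts))
    list(
      counts = counts,
      cell_meta = data.frame(cell = colnames(counts), sample = "sim1",
                             subpopulation = labels),
      gene_meta = data.frame(gene = rownames(counts),
                             is_mito = startsWith(rownames(counts), "mt-")),
      truth = list(cell_labels = labels_named, program_genes = program_genes)
    )
  })
}

#' Simulate UMI counts along pseudotime trajectories
#'
#' Cells are split across `n_lineages` lineages; each cell gets a true
#' pseudotime in \[0, 1\] (rescaled so every lineage spans the full interval)
#' and a chronological `time_point` label (`day1`..`day6` by pseudotime bin).
#' Each lineage receives `n_dynamic_genes` dynamic genes (disjoint across
#' lineages) whose expected expression rises monotonically with pseudotime as
#' `2^(amplitude_log2fc * logistic(steepness * (t - 0.5)))`; all other genes
#' are pseudotime-independent.
#'
#' @param cfg a [sim_config()].
#' @param n_lineages number of lineages.
#' @param n_dynamic_genes dynamic genes planted per lineage.
#' @param amplitude_log2fc log2 amplitude of the dynamic effect (default:
#'   `cfg$program_log2fc`).
#' @param steepness logistic steepness of the pseudotime response.
#' @return list as in [simulate_subpopulation_counts()], with `cell_meta`
#'   columns `lineage`, `pseudotime`, `time_point` and `truth` entries
#'   `lineage_true`, `pseudotime_true`, `dynamic_genes` (per-lineage list).
#' @export
simulate_trajectory_counts <- function(cfg, n_lineages = 2, n_dynamic_genes = 50,
                                       amplitude_log2fc = NULL, steepness = 10) {
  stopifnot(inherits(cfg, "sim_config"))
  .stopifnot_positive_int(n_lineages, "n_lineages")
  .stopifnot_positive_int(n_dynamic_genes, "n_dynamic_genes")
  n_nonmito <- cfg$n_genes - cfg$n_mito_genes
  if (n_dynamic_genes * n_lineages > n_nonmito)
    stop("too many dynamic genes for the gene count", call. = FALSE)
  amp <- amplitude_log2fc %||% cfg$program_log2fc

  withr::with_seed(cfg$seed, {
    base_mean <- .base_gene_means(cfg)
    nonmito_ids <- .gene_ids(n_nonmito)
    # dynamic programs are planted among adequately expressed genes (upper
    # half of baseline means): differentiation programs are expressed genes,
    # and a silent gene cannot carry a pseudotime signal
    expressed <- which(base_mean >= stats::median(base_mean))
    if (length(expressed) < n_dynamic_genes * n_lineages)
      stop("too many dynamic genes for the expressed-gene pool", call. = FALSE)
    dyn_idx <- sample(expressed, n_dynamic_genes * n_lineages)
    dynamic_genes <- split(nonmito_ids[dyn_idx],
                           rep(seq_len(n_lineages), each = n_dynamic_genes))
    names(dynamic_genes) <- paste0("lineage", seq_len(n_lineages))

    lineage <- sample(rep_len(seq_len(n_lineages), cfg$n_cells))
    pt <- stats::runif(cfg$n_cells)
    for (l in seq_len(n_lineages)) {          # each lineage spans [0, 1]
      i <- lineage == l
      r <- range(pt[i])
      pt[i] <- if (diff(r) > 0) (pt[i] - r[1]) / diff(r) else 0
    }
    time_point <- paste0("day", pmin(6L, 1L + floor(pt * 6)))
    libsize <- stats::rlnorm(cfg$n_cells, 0, cfg$libsize_sigma)

    mu <- outer(base_mean, libsize)
    for (l in seq_len(n_lineages)) {
      rows <- match(dynamic_genes[[l]], nonmito_ids)
      cols <- which(lineage == l)
      bump <- 2^(amp * stats::plogis(steepness * (pt[cols] - 0.5)))
      mu[rows, cols] <- mu[rows, cols] * rep(bump, each = length(rows))
    }
    counts <- .sample_counts(cfg, mu)

    cells <- colnames(counts)
    list(
      counts = counts,
      cell_meta = data.frame(cell = cells, sample = "sim1",
                             lineage = paste0("lineage", lineage),
                             pseudotime = pt, time_point = time_point),
      gene_meta = data.frame(gene = rownames(counts),
                             is_mito = startsWith(rownames(counts), "mt-")),
      truth = list(lineage_true = stats::setNames(lineage, cells),
                   pseudotime_true = stats::setNames(pt, cells),
                   dynamic_genes = dynamic_genes)
    )
  })
}
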
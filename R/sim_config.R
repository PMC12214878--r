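#' Simulation configuration for synthetic single-cell count data
#'
#' Holds the knobs of the negative-binomial count simulators: matrix size,
#' number of planted subpopulations, planted-program size and effect,
#' dispersion, per-cell library-size spread and a mitochondrial-fraction
#' range. Counts are drawn from a negative binomial with variance
#' `mu + mu^2 * nb_dispersion`; `nb_dispersion = 0` degenerates to Poisson.
#'
#' @param n_cells number of cells.
#' @param n_genes number of genes (including `n_mito_genes` mitochondrial
#'   genes named with an `mt-` prefix).
#' @param n_subpopulations number of planted subpopulations.
#' @param program_size genes per planted subpopulation program; programs are
#'   pairwise disjoint and exclude mitochondrial genes.
#' @param program_log2fc log2 fold change applied to program genes inside
#'   their subpopulation.
#' @param nb_dispersion negative-binomial dispersion phi
#'   (variance = mu + mu^2 * phi); 0 gives Poisson counts.
#' @param libsize_sigma standard deviation (log scale) of the log-normal
#'   per-cell library size factor.
#' @param mito_fraction_range length-2 interval in \[0, 1\]; each cell's
#'   expected mitochondrial UMI fraction is drawn uniformly from it.
#' @param n_mito_genes number of mitochondrial genes.
#' @param gene_mean_meanlog,gene_mean_sdlog log-normal parameters for
#'   baseline per-gene mean expression.
#' @param seed integer random seed; identical configurations with identical
#'   seeds produce bit-identical data.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells = 600,
                       n_genes = 2000,
                       n_subpopulations = 3,
                       program_size = 50,
                       program_log2fc = 2,
                       nb_dispersion = 0.3,
                       libsize_sigma = 0.3,
                       mito_fraction_range = c(0.01, 0.08),
                       n_mito_genes = 10,
                       gene_mean_meanlog = -0.5,
                       gene_mean_sdlog = 1,
                       seed = 1L) {
  .stopifnot_positive_int(n_cells, "n_cells")
  .stopifnot_positive_int(n_genes, "n_genes")
  .stopifnot_positive_int(n_subpopulations, "n_subpopulations")
  .stopifnot_positive_int(program_size, "program_size")
  if (!is.numeric(nb_dispersion) || nb_dispersion < 0)
    stop("nb_dispersion must be >= 0", call. = FALSE)
  if (!is.numeric(libsize_sigma) || libsize_sigma < 0)
    stop("libsize_sigma must be >= 0", call. = FALSE)
  if (length(mito_fraction_range) != 2 ||
      any(mito_fraction_range < 0) || any(mito_fraction_range > 1) ||
      mito_fraction_range[1] > mito_fraction_range[2])
    stop("mito_fraction_range must be an interval within [0, 1]", call. = FALSE)
  if (n_mito_genes >= n_genes)
    stop("n_mito_genes must be smaller than n_genes", call. = FALSE)
  if (program_size * n_subpopulations > n_genes - n_mito_genes)
    stop("program_size x n_subpopulations exceeds available (non-mito) genes",
         call. = FALSE)
  structure(list(
    n_cells = as.integer(n_cells),
    n_genes = as.integer(n_genes),
    n_subpopulations = as.integer(n_subpopulations),
    program_size = as.integer(program_size),
    program_log2fc = program_log2fc,
    nb_dispersion = nb_dispersion,
    libsize_sigma = libsize_sigma,
    mito_fraction_range = mito_fraction_range,
    n_mito_genes = as.integer(n_mito_genes),
    gene_mean_meanlog = gene_mean_meanlog,
    gene_mean_sdlog = gene_mean_sdlog,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_cells, "cells x", x$n_genes, "genes,",
      x$n_subpopulations, "subpopulations\n")
  cat("  program:", x$program_size, "genes at log2FC", x$program_log2fc, "\n")
  cat("  NB dispersion:", x$nb_dispersion,
      " libsize sigma:", x$libsize_sigma, "\n")
  cat("  mito fraction range: [", x$mito_fraction_range[1], ",",
      x$mito_fraction_range[2], "]  seed:", x$seed, "\n")
  invisible(x)
}
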
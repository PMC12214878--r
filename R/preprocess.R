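#' Quality-control filter on cells
#'
#' Retains cells with more than `min_genes` detected genes (genes with at
#' least one UMI) and a mitochondrial UMI percentage below `max_mito_pct`.
#' Mitochondrial genes are recognized by `mito_pattern` on the gene
#' identifier. Genes are never removed.
#'
#' @param counts genes x cells count matrix with gene rownames.
#' @param min_genes detected-gene threshold (cells must exceed it).
#' @param max_mito_pct mitochondrial percentage threshold (cells must be
#'   below it).
#' @param mito_pattern regular expression flagging mitochondrial genes.
#' @return the count matrix restricted to passing cells.
#' @export
qc_filter <- function(counts, min_genes = 1000, max_mito_pct = 10,
                      mito_pattern = "^mt-") {
  .check_count_matrix(counts)
  is_mito <- grepl(mito_pattern, rownames(counts), ignore.case = TRUE)
  n_detected <- .colsums(counts > 0)
  total <- .colsums(counts)
  mito_pct <- ifelse(total > 0,
                     100 * .colsums(counts[is_mito, , drop = FALSE]) / total, 0)
  keep <- n_detected > min_genes & mito_pct < max_mito_pct
  if (!any(keep))
    stop("qc_filter removed all cells; thresholds too strict for this data",
         call. = FALSE)
  counts[, keep, drop = FALSE]
}

#' Library-size log-normalization
#'
#' `value = ln(1 + scale_factor * count / library_size)` with the library
#' size of a cell being its total UMI count. Zeros stay exactly zero.
#'
#' @param counts genes x cells count matrix.
#' @param scale_factor scaling constant (default 1e4).
#' @return normalized matrix of the same class and dimensions.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  libsize <- .colsums(counts)
  if (any(libsize <= 0))
    stop("all cells must have positive library size", call. = FALSE)
  if (is(counts, "dgCMatrix")) {
    out <- counts
    per_col <- rep.int(libsize, diff(counts@p))
    out@x <- log1p(scale_factor * counts@x / per_col)
    out
  } else {
    log1p(scale_factor * sweep(as.matrix(counts), 2, libsize, "/"))
  }
}

#' Select highly variable genes by standardized dispersion
#'
#' Variance-stabilizing ranking on the raw counts: a loess curve of
#' log10(variance) on log10(mean) predicts each gene's expected standard
#' deviation; counts are standardized with it (clipped above at
#' sqrt(n_cells)) and genes are ranked by the variance of the standardized
#' values. Ties are broken by gene identifier order. Zero-variance genes have
#' standardized dispersion 0 and can never outrank a variable gene.
#'
#' @param counts genes x cells count matrix.
#' @param n number of genes to return.
#' @param span loess span of the mean-variance trend.
#' @return character vector of `n` gene identifiers, ranked most variable
#'   first.
#' @export
select_hvgs <- function(counts, n = 3000, span = 0.3) {
  .check_count_matrix(counts)
  if (n > nrow(counts)) stop("n exceeds the number of genes", call. = FALSE)
  x <- as.matrix(counts)
  mu <- rowMeans(x)
  v <- apply(x, 1, stats::var)
  std_var <- hvg_standardized_variance(x, mu, v, span = span)
  ord <- order(-std_var, rownames(counts))
  rownames(counts)[ord][seq_len(n)]
}

#' @rdname select_hvgs
#' @param x dense count matrix; `mu`, `v` per-gene means and variances.
#' @param mu,v per-gene mean and variance of `x`.
#' @return for `hvg_standardized_variance`: numeric vector of standardized
#'   variances, one per gene.
#' @export
hvg_standardized_variance <- function(x, mu = rowMeans(x),
                                      v = apply(x, 1, stats::var),
                                      span = 0.3) {
  usable <- v > 0 & mu > 0
  exp_sd <- rep(NA_real_, length(mu))
  if (sum(usable) >= 4) {
    fit <- stats::loess(log10(v[usable]) ~ log10(mu[usable]), span = span,
                        degree = 2)
    exp_sd[usable] <- sqrt(10^stats::fitted(fit))
  } else {
    exp_sd[usable] <- sqrt(v[usable])   # too few genes to fit a trend
  }
  n_cells <- ncol(x)
  clip <- sqrt(n_cells)
  std_var <- numeric(length(mu))
  for (i in which(usable)) {
    z <- (x[i, ] - mu[i]) / exp_sd[i]
    z <- pmin(z, clip)
    std_var[i] <- sum(z^2) / (n_cells - 1)
  }
  std_var
}

#' Regress covariates out of normalized expression
#'
#' Per gene, ordinary least squares of expression on the covariates (with
#' intercept); the output holds the residuals, optionally centered and scaled
#' to unit variance per gene for downstream PCA.
#'
#' @param norm genes x cells normalized expression matrix.
#' @param covariates cells x k numeric matrix or data.frame (e.g. cell-cycle
#'   scores); must be full rank together with the intercept.
#' @param scale. center and unit-scale each gene's residuals (default TRUE).
#' @return dense genes x cells residual matrix.
#' @export
regress_out <- function(norm, covariates, scale. = TRUE) {
  x <- as.matrix(norm)
  cov <- as.matrix(covariates)
  if (!all(is.finite(cov))) stop("covariates must be finite", call. = FALSE)
  if (nrow(cov) != ncol(x))
    stop("covariates must have one row per cell", call. = FALSE)
  X <- cbind(intercept = 1, cov)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("covariates are rank deficient (collinear with the intercept or ",
         "each other)", call. = FALSE)
  resid <- t(qr.resid(qrX, t(x)))
  dimnames(resid) <- dimnames(x)
  if (scale.) resid <- scale_rows(resid)
  resid
}

#' Center and unit-scale matrix rows
#'
#' Rows with zero variance become all-zero rather than NaN.
#'
#' @param x numeric matrix.
#' @return matrix with each row centered and divided by its sample SD.
#' @export
scale_rows <- function(x) {
  m <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  out <- (x - m) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out
}

#' Principal component analysis of scaled expression
#'
#' Cells are observations, genes are features (the input is genes x cells and
#' is transposed internally). Returns cell embeddings and the percentage of
#' variance explained per component.
#'
#' @param scaled genes x cells matrix, typically from [regress_out()] or
#'   [scale_rows()].
#' @param n_pcs number of components to keep.
#' @return object of class `pca_result`: list with `embeddings` (cells x
#'   n_pcs) and `percent_variance` (descending, sums to <= 100).
#' @export
run_pca <- function(scaled, n_pcs = 50) {
  x <- t(as.matrix(scaled))
  n_pcs <- min(n_pcs, ncol(x), nrow(x) - 1L)
  p <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  pct <- 100 * p$sdev^2 / sum(p$sdev^2)
  structure(list(
    embeddings = p$x[, seq_len(n_pcs), drop = FALSE],
    percent_variance = pct[seq_len(n_pcs)]
  ), class = "pca_result")
}

#' Choose the number of principal components
#'
#' Implements the percentage-change rule: the change at component `i` is
#' `percent_variance[i-1] - percent_variance[i]` (percentage points); the
#' rule returns the largest `i` whose change exceeds `delta` and whose
#' variance share is itself positive, or `min_pcs` when no component
#' qualifies. Trailing zero-variance components can therefore never alter the
#' answer.
#'
#' @param p a `pca_result` or a numeric vector of percent variance.
#' @param delta change threshold in percentage points (default 0.1).
#' @param min_pcs fallback / minimum component count.
#' @return integer number of components.
#' @export
select_pcs <- function(p, delta = 0.1, min_pcs = 2) {
  pv <- if (inherits(p, "pca_result")) p$percent_variance else as.numeric(p)
  if (length(pv) < 2) stop("need at least 2 components", call. = FALSE)
  if (is.unsorted(rev(pv) - 1e-9))
    stop("percent_variance must be non-increasing", call. = FALSE)
  change <- pv[-length(pv)] - pv[-1]
  eligible <- which(change > delta & pv[-1] > 0) + 1L
  if (length(eligible) == 0) return(as.integer(min_pcs))
  max(eligible)
}

#' Graph-based clustering of cell embeddings
#'
#' Builds a shared-nearest-neighbor (SNN) graph (Jaccard overlap of
#' `n_neighbors`-neighborhoods, pruned below `prune`) and partitions it with
#' seeded modularity optimization (Louvain) at the given resolution.
#'
#' @param embeddings cells x d numeric matrix (e.g. `pca_result$embeddings`).
#' @param resolution modularity resolution; higher gives more clusters
#'   (0.1 for coarse, 0.6 for fine granularity).
#' @param n_neighbors neighborhood size (includes the cell itself).
#' @param prune minimum Jaccard overlap kept as an edge.
#' @param seed integer seed fixing the partition.
#' @return integer cluster labels (1-based) named by cell.
#' @export
cluster_cells <- function(embeddings, resolution = 0.6, n_neighbors = 20,
                          prune = 1 / 15, seed = 1L) {
  emb <- as.matrix(embeddings)
  n <- nrow(emb)
  if (n < n_neighbors)
    stop("fewer cells than n_neighbors", call. = FALSE)
  if (ncol(emb) < 2) stop("need at least 2 embedding dimensions", call. = FALSE)

  d <- as.matrix(stats::dist(emb))
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(n_neighbors)]))
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = n_neighbors),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- A %*% Matrix::t(A)
  jac <- shared / (2 * n_neighbors - shared)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0

  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
  part <- withr::with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  labels <- as.integer(igraph::membership(part))
  names(labels) <- rownames(emb)
  labels
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement of two partitions of the same cells; 1 means
#' identical partitions, 0 is the expectation under independence.
#'
#' @param a,b label vectors of equal length.
#' @return numeric ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
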
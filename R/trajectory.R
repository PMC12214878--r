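#' Remove late cells above a pseudotime cutoff
#'
#' Within the given lineage (or every lineage when `lineage` is NULL), cells
#' with pseudotime strictly above `cutoff` are removed; other lineages are
#' untouched. This reproduces the manual cell-selection step that keeps cells
#' from an early time point with implausibly high pseudotime from driving
#' downstream correlations.
#'
#' @param lin data.frame with columns `cell`, `lineage`, `pseudotime` (and
#'   optionally `time_point`).
#' @param cutoff pseudotime cutoff (cells at the cutoff are kept).
#' @param lineage optional lineage identifier to restrict the filter to.
#' @return the filtered lineage table.
#' @export
apply_pseudotime_cutoff <- function(lin, cutoff, lineage = NULL) {
  stopifnot(all(c("cell", "lineage", "pseudotime") %in% names(lin)),
            is.finite(cutoff))
  drop <- lin$pseudotime > cutoff
  if (!is.null(lineage)) drop <- drop & lin$lineage %in% lineage
  out <- lin[!drop, , drop = FALSE]
  if (nrow(out) == 0)
    stop("pseudotime cutoff removed all cells", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Correlate features with pseudotime along a lineage
#'
#' Pearson product-moment correlation of each feature (gene expression or TF
#' activity) against pseudotime over the cells of one lineage, with the
#' t-based two-sided p value (`t = r * sqrt((n - 2) / (1 - r^2))`) and
#' Bonferroni adjustment over the tested features. Expression features
#' detected (value > 0) in fewer than `min_frac` of the lineage's cells are
#' excluded before testing; activity features are dense, so the gate is
#' skipped when `is_expression = FALSE`. Constant features are excluded with
#' an explicit reason.
#'
#' @param values features x cells numeric matrix.
#' @param lin lineage table (`cell`, `lineage`, `pseudotime`); if several
#'   lineages are present, `lineage` selects one.
#' @param min_frac minimum detection fraction for expression features.
#' @param is_expression apply the detection gate (TRUE for gene expression).
#' @param lineage optional lineage identifier.
#' @return data.frame: `feature`, `r`, `p`, `p_adj`, `frac_detected`,
#'   `tested`, `reason` (NA for tested features).
#' @export
correlate_features <- function(values, lin, min_frac = 0.10,
                               is_expression = TRUE, lineage = NULL) {
  stopifnot(all(c("cell", "lineage", "pseudotime") %in% names(lin)))
  if (!is.null(lineage)) lin <- lin[lin$lineage %in% lineage, , drop = FALSE]
  cells <- intersect(lin$cell, colnames(values))
  if (length(cells) < 3) stop("need at least 3 cells in the lineage", call. = FALSE)
  pt <- lin$pseudotime[match(cells, lin$cell)]
  x <- as.matrix(values[, cells, drop = FALSE])
  n <- length(cells)

  frac <- rowMeans(x > 0)
  reason <- rep(NA_character_, nrow(x))
  tested <- rep(TRUE, nrow(x))
  if (is_expression) {
    gate <- frac < min_frac
    tested[gate] <- FALSE
    reason[gate] <- "below_detection_fraction"
  }
  sds <- apply(x, 1, stats::sd)
  const <- tested & (sds == 0 | stats::sd(pt) == 0)
  tested[const] <- FALSE
  reason[const] <- "constant"

  r <- rep(NA_real_, nrow(x))
  p <- rep(NA_real_, nrow(x))
  if (any(tested)) {
    r[tested] <- as.vector(stats::cor(t(x[tested, , drop = FALSE]), pt))
    t_stat <- r[tested] * sqrt((n - 2) / pmax(1 - r[tested]^2,
                                              .Machine$double.eps))
    p[tested] <- 2 * stats::pt(-abs(t_stat), df = n - 2)
    p[tested][abs(r[tested]) >= 1 - 1e-15] <- 0
  }
  m <- sum(tested)
  out <- data.frame(
    feature = rownames(x), r = r, p = p,
    p_adj = pmin(1, p * m),
    frac_detected = frac, tested = tested, reason = reason
  )
  rownames(out) <- NULL
  out
}

#' Select significantly correlated features and rank them
#'
#' Keeps features with Bonferroni-adjusted p below `alpha` and Pearson r
#' above `min_r`, ordered by decreasing correlation. The resulting ranked
#' table is the input contract for [preranked_gsea()] (use the `r` column as
#' the ranking statistic). An empty selection returns an empty table, with a
#' message, rather than an error.
#'
#' @param tab output of [correlate_features()].
#' @param alpha adjusted-p threshold (exclusive).
#' @param min_r correlation threshold (exclusive).
#' @return subset of `tab` with a `rank` column, best first.
#' @export
select_and_rank <- function(tab, alpha = 0.05, min_r = 0.25) {
  stopifnot(all(c("feature", "r", "p_adj", "tested") %in% names(tab)))
  keep <- tab$tested & !is.na(tab$p_adj) & tab$p_adj < alpha & tab$r > min_r
  out <- tab[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    message("no features pass the correlation selection")
    out$rank <- integer(0)
    return(out)
  }
  out <- out[order(-out$r, out$feature), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Naive MST-based pseudotime (demo plumbing only)
#'
#' A deliberately simple stand-in for a dedicated trajectory-inference tool,
#' shipped so demonstration pipelines can run self-contained: cluster
#' centroids are joined by a minimum spanning tree, each root-to-leaf path
#' defines a lineage, and a cell's pseudotime is its cluster's tree distance
#' from the root plus the cell's projection onto the incoming tree edge,
#' rescaled to \[0, 1\] per lineage. This is not a validated trajectory
#' method; real analyses should supply lineages and pseudotimes from a
#' dedicated tool.
#'
#' @param embeddings cells x d matrix.
#' @param cluster_labels per-cell cluster labels (named or in row order).
#' @param start_cluster root cluster of the trajectory.
#' @return data.frame: `cell`, `lineage`, `pseudotime` (one row per cell per
#'   lineage containing its cluster).
#' @export
naive_pseudotime <- function(embeddings, cluster_labels, start_cluster) {
  emb <- as.matrix(embeddings)
  labs <- if (!is.null(names(cluster_labels)) && !is.null(rownames(emb)))
    cluster_labels[rownames(emb)] else cluster_labels
  stopifnot(length(labs) == nrow(emb))
  clusters <- sort(unique(labs))
  if (!start_cluster %in% clusters) stop("unknown start cluster", call. = FALSE)
  centroids <- t(vapply(clusters, function(k)
    colMeans(emb[labs == k, , drop = FALSE]), numeric(ncol(emb))))
  rownames(centroids) <- as.character(clusters)

  d <- as.matrix(stats::dist(centroids))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g)
  root <- as.character(start_cluster)
  dist_from_root <- igraph::distances(tree, v = root)[1, ]
  leaves <- names(which(igraph::degree(tree) == 1))
  leaves <- setdiff(leaves, root)
  if (length(leaves) == 0) leaves <- root

  res <- lapply(seq_along(leaves), function(li) {
    path <- igraph::shortest_paths(tree, from = root, to = leaves[li])$vpath[[1]]
    path_clusters <- names(path)
    cells_in <- which(as.character(labs) %in% path_clusters)
    pt <- numeric(length(cells_in))
    for (ci in seq_along(cells_in)) {
      i <- cells_in[ci]
      k <- as.character(labs[i])
      base <- dist_from_root[k]
      pos <- match(k, path_clusters)
      if (pos > 1) {          # project onto the incoming tree edge
        prev <- centroids[path_clusters[pos - 1], ]
        here <- centroids[k, ]
        edge <- here - prev
        proj <- sum((emb[i, ] - here) * edge) / sqrt(sum(edge^2))
        pt[ci] <- base + proj
      } else {
        pt[ci] <- base + sqrt(sum((emb[i, ] - centroids[k, ])^2)) *
          sign(sum(emb[i, ] - centroids[k, ]))
      }
    }
    pt <- pt - min(pt)
    if (max(pt) > 0) pt <- pt / max(pt)
    data.frame(cell = rownames(emb)[cells_in],
               lineage = paste0("lineage", li), pseudotime = pt)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
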
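#' Gene signature Z-scores per cell and per cluster
#'
#' Each gene's log-normalized expression is standardized across cells,
#' `z = (x - mu) / sigma` with the sample standard deviation; a cell's
#' signature score is the mean `z` over the signature's genes, and a
#' cluster's score is the mean over its cells. Signature genes absent from
#' the matrix or with zero variance are dropped with a warning.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param signatures named list of gene vectors (or one character vector).
#' @param cluster_labels optional per-cell labels (named or in column order)
#'   for per-cluster mean scores.
#' @return list with `cell_scores` (signatures x cells matrix),
#'   `cluster_scores` (signatures x clusters matrix or NULL) and `dropped`
#'   (named list of genes dropped per signature).
#' @export
signature_zscore <- function(norm, signatures, cluster_labels = NULL) {
  if (!is.list(signatures)) signatures <- list(signature = signatures)
  if (is.null(names(signatures)))
    names(signatures) <- paste0("signature", seq_along(signatures))
  x <- as.matrix(norm)
  mu <- rowMeans(x)
  sigma <- apply(x, 1, stats::sd)

  cell_scores <- matrix(NA_real_, nrow = length(signatures), ncol = ncol(x),
                        dimnames = list(names(signatures), colnames(x)))
  dropped <- vector("list", length(signatures))
  names(dropped) <- names(signatures)
  for (nm in names(signatures)) {
    genes <- unique(signatures[[nm]])
    missing <- setdiff(genes, rownames(x))
    present <- intersect(genes, rownames(x))
    constant <- present[sigma[present] == 0]
    usable <- setdiff(present, constant)
    dropped[[nm]] <- list(unresolved = missing, zero_variance = constant)
    if (length(missing) + length(constant) > 0)
      warning(sprintf("signature '%s': dropped %d unresolved and %d zero-variance genes",
                      nm, length(missing), length(constant)), call. = FALSE)
    if (length(usable) == 0)
      stop(sprintf("signature '%s' has no resolvable non-constant genes", nm),
           call. = FALSE)
    z <- (x[usable, , drop = FALSE] - mu[usable]) / sigma[usable]
    cell_scores[nm, ] <- colMeans(z)
  }

  cluster_scores <- NULL
  if (!is.null(cluster_labels)) {
    labs <- if (!is.null(names(cluster_labels)) && !is.null(colnames(x)))
      cluster_labels[colnames(x)] else cluster_labels
    stopifnot(length(labs) == ncol(x))
    groups <- split(seq_len(ncol(x)), labs)
    cluster_scores <- vapply(groups, function(i)
      rowMeans(cell_scores[, i, drop = FALSE]), numeric(nrow(cell_scores)))
    if (nrow(cell_scores) == 1)
      cluster_scores <- matrix(cluster_scores, nrow = 1,
                               dimnames = list(rownames(cell_scores),
                                               names(groups)))
  }
  list(cell_scores = cell_scores, cluster_scores = cluster_scores,
       dropped = dropped)
}

#' Differentially expressed genes between two cell groups
#'
#' Marker detection at the field's standard criteria: genes detected in at
#' least `min_pct` of cells in either group are tested with a two-sided
#' Wilcoxon rank-sum test on the normalized values; the fold change is the
#' ratio of group means on the un-logged (`expm1`) scale with a pseudocount;
#' p values are Bonferroni-adjusted over the tested genes. A gene is flagged
#' as a marker (`is_deg`) when its fold change reaches `min_fc` (with
#' `positive_only = FALSE`, in either direction), its adjusted p value is at
#' most `alpha`, and — with `positive_only` — the change favors group A.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param group_a,group_b disjoint cell identifier (or column index) vectors.
#' @param min_pct minimum detection fraction in at least one group.
#' @param min_fc fold-change threshold (natural-ratio scale).
#' @param alpha adjusted-p threshold for the marker flag.
#' @param positive_only only flag genes up in group A.
#' @param pseudocount added to both group means before forming the ratio.
#' @return data.frame with one row per tested gene: `gene`, `log2fc`, `fc`,
#'   `pct_a`, `pct_b`, `p`, `p_adj`, `is_deg`, ordered by p value.
#' @export
call_degs <- function(norm, group_a, group_b, min_pct = 0.25, min_fc = 1.5,
                      alpha = 0.05, positive_only = TRUE, pseudocount = 1) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  if (length(intersect(group_a, group_b)) > 0)
    stop("groups overlap", call. = FALSE)
  xa <- as.matrix(norm[, group_a, drop = FALSE])
  xb <- as.matrix(norm[, group_b, drop = FALSE])

  pct_a <- rowMeans(xa > 0)
  pct_b <- rowMeans(xb > 0)
  tested <- which(pct_a >= min_pct | pct_b >= min_pct)
  if (length(tested) == 0)
    return(data.frame(gene = character(0), log2fc = numeric(0), fc = numeric(0),
                      pct_a = numeric(0), pct_b = numeric(0), p = numeric(0),
                      p_adj = numeric(0), is_deg = logical(0)))

  p <- vapply(tested, function(i) {
    suppressWarnings(stats::wilcox.test(xa[i, ], xb[i, ], exact = FALSE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1    # identical constant groups
  fc <- (rowMeans(expm1(xa[tested, , drop = FALSE])) + pseudocount) /
        (rowMeans(expm1(xb[tested, , drop = FALSE])) + pseudocount)
  p_adj <- pmin(1, p * length(tested))

  effect_ok <- if (positive_only) fc >= min_fc else pmax(fc, 1 / fc) >= min_fc
  out <- data.frame(
    gene = rownames(norm)[tested],
    log2fc = log2(fc), fc = fc,
    pct_a = pct_a[tested], pct_b = pct_b[tested],
    p = p, p_adj = p_adj,
    is_deg = effect_ok & p_adj <= alpha
  )
  rownames(out) <- NULL
  out[order(out$p, out$gene), ]
}

#' Rank enriched pathways on significance and effect size
#'
#' Only significant pathways (fold change above `fc_min` and adjusted p
#' below `alpha`) enter the ranking. The default combines the ascending rank
#' of the q value with the descending rank of the fold change; the pathway
#' with the smallest combined rank comes first, ties broken by q value then
#' by name. `method = "literal_sum"` instead scores each pathway by the raw
#' sum `q + fc` (larger first), an alternative reading of the same rule.
#'
#' @param tab data.frame with columns `pathway`, `q`, `fc`.
#' @param fc_min fold-change entry criterion (exclusive).
#' @param alpha adjusted-p entry criterion (exclusive).
#' @param method `"rank_sum"` (default) or `"literal_sum"`.
#' @return data.frame of retained pathways with `score` and `rank`, best
#'   first.
#' @export
rank_pathways <- function(tab, fc_min = 1, alpha = 0.05,
                          method = c("rank_sum", "literal_sum")) {
  method <- match.arg(method)
  stopifnot(all(c("pathway", "q", "fc") %in% names(tab)))
  if (any(tab$q < 0 | tab$q > 1)) stop("q values must be in [0, 1]", call. = FALSE)
  if (any(!is.finite(tab$fc))) stop("fold changes must be finite", call. = FALSE)
  keep <- tab$fc > fc_min & tab$q < alpha
  out <- tab[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    out$score <- numeric(0); out$rank <- integer(0)
    return(out)
  }
  if (method == "rank_sum") {
    out$score <- rank(out$q, ties.method = "average") +
      rank(-out$fc, ties.method = "average")
    ord <- order(out$score, out$q, out$pathway)
  } else {
    out$score <- out$q + out$fc
    ord <- order(-out$score, out$q, out$pathway)
  }
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Transcription factor activity by univariate linear modeling
#'
#' For every (TF, cell) pair, the cell's expression profile over all genes is
#' regressed on the TF's regulon weight vector (weight 0 outside the regulon)
#' with an intercept; the activity is the t-statistic of the slope,
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `r` the Pearson correlation
#' between expression and weights over the `n` genes. Regulons with fewer
#' than `min_targets` targets resolvable in the matrix are excluded.
#'
#' @param expr genes x cells expression matrix (typically centered; the
#'   intercept makes the statistic invariant to per-cell location shifts).
#' @param regulons data.frame with columns `tf`, `target`, `weight`.
#' @param min_targets minimum resolvable targets per TF (default 20).
#' @param perfect_fit_sentinel value (with the slope's sign) reported when a
#'   regression fits perfectly and the t-statistic diverges.
#' @return TFs x cells activity matrix.
#' @export
tf_activity_ulm <- function(expr, regulons, min_targets = 20,
                            perfect_fit_sentinel = 1e6) {
  stopifnot(all(c("tf", "target", "weight") %in% names(regulons)))
  x <- as.matrix(expr)
  regs <- regulons[regulons$target %in% rownames(x), , drop = FALSE]
  n_targets <- table(regs$tf)
  keep_tfs <- names(n_targets)[n_targets >= min_targets]
  if (length(keep_tfs) == 0)
    stop("no regulon has enough resolvable targets", call. = FALSE)
  regs <- regs[regs$tf %in% keep_tfs, , drop = FALSE]

  W <- matrix(0, nrow = nrow(x), ncol = length(keep_tfs),
              dimnames = list(rownames(x), sort(keep_tfs)))
  W[cbind(match(regs$target, rownames(x)), match(regs$tf, colnames(W)))] <-
    regs$weight

  n <- nrow(x)
  r <- suppressWarnings(stats::cor(W, x))     # TFs x cells
  bad <- !is.finite(r)
  if (any(bad)) {
    warning("constant expression column(s); their activities set to 0",
            call. = FALSE)
    r[bad] <- 0
  }
  perfect <- abs(r) >= 1 - 1e-12
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  if (any(perfect)) {
    warning("perfect regulon fit; activity set to the sentinel value",
            call. = FALSE)
    t_stat[perfect] <- sign(r[perfect]) * perfect_fit_sentinel
  }
  dimnames(t_stat) <- list(colnames(W), colnames(x))
  t_stat
}

#' Differentially active transcription factors per cluster
#'
#' Activities are centered and unit-scaled per TF across cells, then each
#' cluster is compared against all other cells with the Wilcoxon rank-sum
#' test. There is no detection-fraction gate (activities are dense); the
#' effect size is the difference of scaled means, and p values are
#' Bonferroni-adjusted over the TFs within each comparison.
#'
#' @param activities TFs x cells matrix from [tf_activity_ulm()].
#' @param cluster_labels per-cell labels (named or in column order).
#' @param alpha adjusted-p threshold for the `is_da` flag.
#' @param positive_only only flag TFs more active in the cluster.
#' @return data.frame: `cluster`, `tf`, `mean_diff`, `p`, `p_adj`, `is_da`.
#' @export
differential_activity <- function(activities, cluster_labels, alpha = 0.05,
                                  positive_only = TRUE) {
  x <- as.matrix(activities)
  labs <- if (!is.null(names(cluster_labels)) && !is.null(colnames(x)))
    cluster_labels[colnames(x)] else cluster_labels
  stopifnot(length(labs) == ncol(x))
  if (length(unique(labs)) < 2)
    stop("need at least 2 clusters", call. = FALSE)
  scaled <- scale_rows(x)

  res <- lapply(sort(unique(labs)), function(k) {
    in_k <- labs == k
    p <- apply(scaled, 1, function(v)
      suppressWarnings(stats::wilcox.test(v[in_k], v[!in_k],
                                          exact = FALSE)$p.value))
    p[is.na(p)] <- 1
    md <- rowMeans(scaled[, in_k, drop = FALSE]) -
      rowMeans(scaled[, !in_k, drop = FALSE])
    data.frame(cluster = k, tf = rownames(x), mean_diff = md, p = p,
               p_adj = pmin(1, p * nrow(x)))
  })
  out <- do.call(rbind, res)
  out$is_da <- out$p_adj <= alpha & (!positive_only | out$mean_diff > 0)
  rownames(out) <- NULL
  out
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score for member
# positions `hit_idx` (indices into the descending-ranked statistic `s_abs`).
.gsea_es <- function(s_abs, hit_idx, n) {
  hit <- logical(n)
  hit[hit_idx] <- TRUE
  w <- s_abs * hit
  p_hit <- cumsum(w) / sum(w)
  n_miss <- n - length(hit_idx)
  p_miss <- if (n_miss == 0) rep(0, n) else cumsum(!hit) / n_miss
  dev <- p_hit - p_miss
  dev[which.max(abs(dev))]
}

#' Pre-ranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic (weights are the
#' absolute ranking statistic) over genes ordered by decreasing statistic.
#' Significance comes from a gene-permutation null: `n_perm` random sets of
#' the same size. `p = (1 + #{null beyond ES}) / (n_perm + 1)` using the tail
#' matching the sign of ES, `NES = ES / mean(|null ES| of the same sign)`,
#' and q values are Benjamini-Hochberg over the scored sets. Sets with fewer
#' than `min_set_size` resolvable genes are skipped with a warning.
#'
#' @param ranked_genes named numeric vector: ranking statistic per gene
#'   (e.g. pseudotime correlation coefficients).
#' @param sets named list of gene vectors.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation null.
#' @param min_set_size minimum resolvable set size.
#' @return data.frame: `pathway`, `size`, `es`, `nes`, `p`, `q`.
#' @export
preranked_gsea <- function(ranked_genes, sets, n_perm = 1000, seed = 1L,
                           min_set_size = 5) {
  stopifnot(!is.null(names(ranked_genes)), all(is.finite(ranked_genes)))
  ord <- order(-ranked_genes, names(ranked_genes))
  s <- ranked_genes[ord]
  genes <- names(s)
  s_abs <- abs(s)
  n <- length(s)

  sizes <- vapply(sets, function(g) length(intersect(g, genes)), integer(1))
  skip <- sizes < min_set_size
  if (any(skip))
    warning(sprintf("skipping %d set(s) smaller than %d resolvable genes",
                    sum(skip), min_set_size), call. = FALSE)
  use <- names(sets)[!skip]
  if (length(use) == 0)
    return(data.frame(pathway = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), p = numeric(0),
                      q = numeric(0)))

  # the gene-permutation null depends only on set size: compute once per size
  null_by_size <- withr::with_seed(seed, {
    out <- list()
    for (k in sort(unique(sizes[use]))) {
      out[[as.character(k)]] <- vapply(seq_len(n_perm), function(i)
        .gsea_es(s_abs, sample.int(n, k), n), numeric(1))
    }
    out
  })

  res <- lapply(use, function(nm) {
    hit_idx <- which(genes %in% sets[[nm]])
    es <- .gsea_es(s_abs, hit_idx, n)
    null <- null_by_size[[as.character(length(hit_idx))]]
    if (es >= 0) {
      p <- (1 + sum(null >= es)) / (n_perm + 1)
      same <- null[null > 0]
    } else {
      p <- (1 + sum(null <= es)) / (n_perm + 1)
      same <- null[null < 0]
    }
    nes <- if (length(same) > 0) es / mean(abs(same)) else NA_real_
    data.frame(pathway = nm, size = length(hit_idx), es = es, nes = nes, p = p)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[order(out$p, -abs(out$nes), out$pathway), ]
}
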
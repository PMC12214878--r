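mk_norm <- function(n_genes = 30, n_cells = 40, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(abs(rnorm(n_genes * n_cells)), nrow = n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("c%03d", seq_len(n_cells))))
    m
  })
}

test_that("signature Z-scores match hand computation and the loop oracle", {
  two <- matrix(c(0, 2), nrow = 1, dimnames = list("g1", c("c1", "c2")))
  z <- signature_zscore(two, list(sig = "g1"))
  expect_equal(as.numeric(z$cell_scores), c(-1, 1) / sqrt(2), tolerance = 1e-4)

  m <- mk_norm(seed = 2)
  sig <- rownames(m)[c(3, 7, 11)]
  z <- signature_zscore(m, list(s = sig))
  expect_equal(as.numeric(z$cell_scores), oracle_signature_scores(m, sig),
               tolerance = 1e-12)

  # all-genes signature over a single all-cells cluster averages to zero
  zc <- signature_zscore(m, list(all = rownames(m)),
                         cluster_labels = rep(1, ncol(m)))
  expect_equal(as.numeric(zc$cluster_scores), 0, tolerance = 1e-12)
})

test_that("Z-scoring is invariant to per-gene affine transforms and drops bad genes", {
  m <- mk_norm(seed = 3)
  sig <- rownames(m)[1:5]
  base <- signature_zscore(m, list(s = sig))$cell_scores
  shifted <- m * 3.7 + 2.2
  expect_equal(signature_zscore(shifted, list(s = sig))$cell_scores, base,
               tolerance = 1e-12)

  m2 <- m; m2[1, ] <- 5                        # zero variance gene
  expect_warning(z <- signature_zscore(m2, list(s = c(sig, "nope"))),
                 "dropped 1 unresolved and 1 zero-variance")
  expect_equal(z$dropped$s$zero_variance, rownames(m)[1])
  m3 <- m; m3[sig, ] <- 1
  expect_error(suppressWarnings(signature_zscore(m3, list(s = sig))),
               "no resolvable")
})

test_that("marker calling honors gates, direction and Bonferroni", {
  withr::with_seed(4, {
    m <- mk_norm(n_genes = 40, n_cells = 120, seed = 4)
    a <- colnames(m)[1:60]; b <- colnames(m)[61:120]
    m["g001", a] <- m["g001", a] + 2             # planted up in A
    m["g002", ] <- 0
    pos <- withr::with_seed(9, sample(120, 10))  # ~8% detection both groups
    m["g002", pos] <- 10
  })
  degs <- call_degs(m, a, b)
  expect_true(degs$is_deg[degs$gene == "g001"])
  expect_false("g002" %in% degs$gene)            # min.pct gate
  m_tested <- nrow(degs)
  expect_equal(degs$p_adj, pmin(1, degs$p * m_tested))
  expect_true(all(degs$p_adj >= degs$p))

  flipped <- call_degs(m, b, a, positive_only = FALSE)
  i <- match(degs$gene, flipped$gene)
  expect_equal(flipped$fc[i], 1 / degs$fc, tolerance = 1e-12)
  expect_equal(flipped$log2fc[i], -degs$log2fc, tolerance = 1e-12)

  expect_error(call_degs(m, a, c(b, a[1])), "overlap")
  expect_error(call_degs(m, character(0), b), "non-empty")
})

test_that("pathway ranking combines q and FC ranks with stated tie-breaks", {
  tab <- data.frame(
    pathway = c("best", "goodq", "goodfc", "middling", "insig"),
    q = c(0.001, 0.002, 0.04, 0.03, 0.5),
    fc = c(5, 2, 4.5, 2.5, 10))
  r <- rank_pathways(tab)
  expect_equal(r$pathway[1], "best")             # dominates both criteria
  expect_false("insig" %in% r$pathway)           # q entry criterion

  # brute-force rank-sum enumeration on the retained rows
  kept <- tab[tab$fc > 1 & tab$q < 0.05, ]
  score <- rank(kept$q) + rank(-kept$fc)
  expect_equal(r$score, sort(score))
  expect_equal(r$pathway, kept$pathway[order(score, kept$q, kept$pathway)])

  r2 <- rank_pathways(data.frame(pathway = c("a", "b"), q = c(0.01, 0.01),
                                 fc = c(2, 2)))
  expect_equal(r2$pathway, c("a", "b"))          # name tie-break
  expect_equal(rank_pathways(data.frame(pathway = "x", q = 0.2, fc = 0.5)) |>
                 nrow(), 0)
  lit <- rank_pathways(tab, method = "literal_sum")
  expect_equal(lit$pathway[1], "best")
})

test_that("ulm activity equals the per-regression t-statistic oracle", {
  rs <- simulate_regulon_data(n_tfs = 2, targets_per_tf = 25, n_cells = 12,
                              activity_scale = 1.5, n_background_genes = 75,
                              seed = 5)
  act <- tf_activity_ulm(rs$expr, rs$regulons)
  for (tf in rownames(act)) {
    w <- numeric(nrow(rs$expr))
    names(w) <- rownames(rs$expr)
    tf_rows <- rs$regulons$tf == tf
    w[rs$regulons$target[tf_rows]] <- rs$regulons$weight[tf_rows]
    expect_equal(act[tf, ], oracle_ulm(rs$expr, w), tolerance = 1e-10)
  }
})

test_that("ulm handles zero correlation, perfect fit and the target filter", {
  n <- 100
  w <- c(rep(1, 25), rep(0, 75))
  genes <- sprintf("g%03d", 1:n)
  regs <- data.frame(tf = "TF1", target = genes[1:25], weight = 1)
  # expression orthogonal to the weight vector: r = 0 -> activity 0
  y <- rep(c(1, -1), 50)
  y <- y - mean(y)
  y <- y - sum(y * (w - mean(w))) / sum((w - mean(w))^2) * (w - mean(w))
  expr0 <- matrix(y, ncol = 1, dimnames = list(genes, "c1"))
  expect_equal(as.numeric(tf_activity_ulm(expr0, regs)), 0, tolerance = 1e-10)

  # expression exactly proportional to the weights: sentinel
  exprp <- matrix(w, ncol = 1, dimnames = list(genes, "c1"))
  expect_warning(actp <- tf_activity_ulm(exprp, regs), "perfect")
  expect_equal(as.numeric(actp), 1e6)

  regs_small <- data.frame(tf = "TFsmall", target = genes[1:10], weight = 1)
  expect_error(tf_activity_ulm(expr0, regs_small), "enough resolvable targets")
})

test_that("differential activity flags the planted cluster-specific TF", {
  hits <- 0L
  for (seed in 1:5) {
    rs <- simulate_regulon_data(n_tfs = 4, targets_per_tf = 25, n_cells = 150,
                                activity_scale = 0, seed = seed)
    labs <- rep(1:3, each = 50)
    act <- tf_activity_ulm(rs$expr, rs$regulons)
    act["TF01", labs == 2] <- act["TF01", labs == 2] + 5   # plant activity
    da <- differential_activity(act, labs)
    flagged <- da[da$is_da, ]
    if (identical(flagged$tf, "TF01") && identical(flagged$cluster, 2L))
      hits <- hits + 1L
  }
  expect_gte(hits, 5 * 0.95 - 1e-9)

  # centering identity on the scaled activities
  rs <- simulate_regulon_data(n_tfs = 3, targets_per_tf = 25, n_cells = 60,
                              activity_scale = 1, seed = 7)
  act <- tf_activity_ulm(rs$expr, rs$regulons)
  expect_equal(as.numeric(rowMeans(scale_rows(act))), rep(0, 3),
               tolerance = 1e-12)
  expect_error(differential_activity(act, rep(1, 60)), "2 clusters")
})

test_that("GSEA enrichment score matches the brute-force running sum", {
  withr::with_seed(8, {
    stat <- setNames(rnorm(20), sprintf("g%02d", 1:20))
  })
  set <- names(sort(stat, decreasing = TRUE))[c(1, 3, 5, 7, 9)]
  res <- suppressWarnings(
    preranked_gsea(stat, list(s = set), n_perm = 50, seed = 1))
  expect_equal(res$es, oracle_gsea_es(stat, set), tolerance = 1e-12)

  # invariance to monotone rescaling that keeps order and sign pattern
  stat2 <- sign(stat) * abs(stat)               # identity check baseline
  res2 <- preranked_gsea(stat2, list(s = set), n_perm = 50, seed = 1)
  expect_equal(res2$es, res$es)
})

test_that("GSEA attains the permutation floor for a top-of-list set", {
  withr::with_seed(9, {
    stat <- setNames(sort(rnorm(100, 1), decreasing = TRUE),
                     sprintf("g%03d", 1:100))
  })
  set <- names(stat)[1:10]
  res <- preranked_gsea(stat, list(top = set), n_perm = 200, seed = 2)
  expect_gt(res$es, 0)
  expect_equal(res$p, 1 / 201)
  expect_gt(res$nes, 1)

  small <- list(tiny = names(stat)[1:3])
  expect_warning(out <- preranked_gsea(stat, small, n_perm = 50, seed = 1),
                 "skipping")
  expect_equal(nrow(out), 0)
})

test_that("GSEA agrees with an independent implementation on the score", {
  skip_if_not_installed("fgsea")
  withr::with_seed(10, {
    stat <- setNames(rnorm(200), sprintf("g%03d", 1:200))
    sets <- list(a = sample(names(stat), 15), b = sample(names(stat), 30))
  })
  mine <- preranked_gsea(stat, sets, n_perm = 100, seed = 3)
  ref <- suppressWarnings(fgsea::fgsea(sets, stat, nperm = 1000))
  for (nm in names(sets)) {
    expect_equal(mine$es[mine$pathway == nm], ref$ES[ref$pathway == nm],
                 tolerance = 1e-6)
  }
})
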
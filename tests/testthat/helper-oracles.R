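# Independent brute-force oracles. These deliberately re-derive each quantity
# along a different computational path from the package implementation.

# Hamming distance by explicit character comparison (N counts as mismatch
# wherever it differs from the whitelist base).
oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(ca != cb)
}

# Levenshtein distance by dynamic programming (independent of utils::adist).
oracle_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  d <- matrix(0, na + 1, nb + 1)
  d[, 1] <- 0:na
  d[1, ] <- 0:nb
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    cost <- if (ca[i] == cb[j]) 0 else 1
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1, d[i + 1, j] + 1, d[i, j] + cost)
  }
  d[na + 1, nb + 1]
}

# Stage-by-stage barcode assignment for one read, given the full whitelist
# and the set of matched barcodes observed in stages a/b.
oracle_assign_read <- function(bc, whitelist, matched, rescue_max_edit = 2) {
  if (bc %in% whitelist) return(list(barcode = bc, method = "exact"))
  dists <- vapply(whitelist, oracle_hamming, numeric(1), a = bc)
  at1 <- which(dists == 1)
  if (length(at1) == 1)
    return(list(barcode = whitelist[at1], method = "one_mismatch"))
  if (length(matched) > 0) {
    ed <- vapply(matched, oracle_levenshtein, numeric(1), a = bc)
    best <- min(ed)
    if (best <= rescue_max_edit && sum(ed == best) == 1)
      return(list(barcode = matched[which.min(ed)], method = "alignment_rescue"))
  }
  list(barcode = NA_character_, method = "unassigned")
}

# Exhaustive scan of the signed point-to-chord distance on the log-log curve.
oracle_knee <- function(counts) {
  cnt <- sort(counts, decreasing = TRUE)
  n <- length(cnt)
  x <- log10(seq_len(n)); y <- log10(pmax(cnt, 1e-12))
  p1 <- c(x[1], y[1]); p2 <- c(x[n], y[n])
  u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  best <- -Inf; best_i <- 1L
  for (i in seq_len(n)) {
    v <- c(x[i], y[i]) - p1
    perp <- v - sum(v * u) * u               # rejection from the chord
    dist <- sqrt(sum(perp^2))
    chord_y <- p1[2] + (x[i] - p1[1]) / u[1] * u[2]
    signed <- if (is.nan(dist) || y[i] >= chord_y) dist else -dist
    if (signed > best) { best <- signed; best_i <- i }
  }
  best_i
}

# Distinct-UMI tally with nested loops and sets.
oracle_flatten <- function(df) {
  cells <- sort(unique(df$cell)); genes <- sort(unique(df$gene))
  m <- matrix(0, length(genes), length(cells), dimnames = list(genes, cells))
  for (cl in cells) for (g in genes) {
    u <- df$umi[df$cell == cl & df$gene == g]
    m[g, cl] <- length(unique(u))
  }
  m
}

# Upper-tail Poisson probability by direct pmf summation.
oracle_poisson_tail <- function(k, lambda) {
  if (k <= 0) return(1)
  upper <- max(k, ceiling(lambda)) + ceiling(20 * sqrt(lambda + 1)) + 200
  sum(stats::dpois(k:upper, lambda))
}

# Element-wise Z-score / signature-score recomputation with explicit loops.
oracle_signature_scores <- function(norm, genes) {
  x <- as.matrix(norm)
  genes <- intersect(genes, rownames(x))
  genes <- genes[apply(x[genes, , drop = FALSE], 1, stats::sd) > 0]
  z <- matrix(NA_real_, length(genes), ncol(x))
  for (gi in seq_along(genes)) {
    v <- x[genes[gi], ]
    z[gi, ] <- (v - mean(v)) / stats::sd(v)
  }
  colMeans(z)
}

oracle_log_normalize <- function(counts, scale_factor = 1e4) {
  x <- as.matrix(counts)
  lib <- colSums(x)
  out <- x
  for (j in seq_len(ncol(x))) for (i in seq_len(nrow(x)))
    out[i, j] <- log(1 + scale_factor * x[i, j] / lib[j])
  out
}

# Per-gene OLS residuals through the normal equations.
oracle_regress <- function(norm, covariates) {
  x <- as.matrix(norm)
  X <- cbind(1, as.matrix(covariates))
  beta <- solve(t(X) %*% X) %*% t(X) %*% t(x)
  t(t(x) - X %*% beta)
}

# ulm activity through lm() per (TF, cell).
oracle_ulm <- function(expr, w_vec) {
  apply(expr, 2, function(y) {
    fit <- summary(stats::lm(y ~ w_vec))
    fit$coefficients["w_vec", "t value"]
  })
}

# Pearson r / p through cor.test per feature.
oracle_correlate <- function(values, pt) {
  t(apply(values, 1, function(v) {
    ct <- stats::cor.test(v, pt)
    c(r = unname(ct$estimate), p = ct$p.value)
  }))
}

# Step-by-step weighted running-sum enrichment score.
oracle_gsea_es <- function(stat, set) {
  ord <- order(-stat, names(stat))
  s <- stat[ord]
  hits <- names(s) %in% set
  nr <- sum(abs(s[hits]))
  n_miss <- sum(!hits)
  run <- 0; best <- 0
  for (i in seq_along(s)) {
    run <- run + if (hits[i]) abs(s[[i]]) / nr else -1 / n_miss
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}
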
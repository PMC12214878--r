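mk_reads <- function(barcodes) {
  data.frame(read_id = sprintf("r%03d", seq_along(barcodes)),
             barcode = barcodes,
             umi = strrep("A", 4), gene = "g1")
}

test_that("deconvolution handles exact, one-mismatch, ambiguous and tied reads", {
  a <- deconvolute_barcodes(mk_reads("AAAA"), "AAAA")
  expect_equal(a$assigned_barcode, "AAAA")
  expect_equal(a$method, "exact")

  wl <- c("AAAA", "TTTT")
  a <- deconvolute_barcodes(mk_reads(c("AAAA", "TTTT", "AAAT", "AATT")), wl)
  expect_equal(a$assigned_barcode[3], "AAAA")
  expect_equal(a$method[3], "one_mismatch")
  # AATT is at Hamming 2 from both matched barcodes; the rescue tie at equal
  # edit distance leaves it unassigned
  expect_equal(a$method[4], "unassigned")
  expect_true(is.na(a$assigned_barcode[4]))

  # two whitelist barcodes at distance 1: ambiguous at the mismatch stage,
  # and the rescue tie leaves it unassigned
  a <- deconvolute_barcodes(mk_reads(c("AAAA", "AAAT", "AAAC")), c("AAAA", "AAAT"))
  expect_equal(a$method, c("exact", "exact", "unassigned"))
})

test_that("N bases count as mismatches and never match exactly", {
  a <- deconvolute_barcodes(mk_reads("AANA"), c("AAAA", "TTTT"))
  expect_equal(a$assigned_barcode, "AAAA")
  expect_equal(a$method, "one_mismatch")
  a <- deconvolute_barcodes(mk_reads(c("AAAA", "ANNA")), c("AAAA", "TTTT"))
  expect_equal(a$method[2], "alignment_rescue")   # 2 edits to the matched AAAA
})

test_that("rescue targets observed matched barcodes within the edit budget", {
  wl <- c("AAAAAA", "TTTTTT")
  reads <- mk_reads(c("AAAAAA", "AACCAA", "GGGGGG"))
  a <- deconvolute_barcodes(reads, wl, rescue_max_edit = 2)
  expect_equal(a$method, c("exact", "alignment_rescue", "unassigned"))
  expect_equal(a$assigned_barcode[2], "AAAAAA")

  # without any matched barcode there is nothing to rescue against
  b <- deconvolute_barcodes(mk_reads("AACCAA"), wl)
  expect_equal(b$method, "unassigned")
})

test_that("deconvolution is order-independent and idempotent over reads", {
  dd <- simulate_ddseq_reads(whitelist_size = 20, n_cells = 10,
                             reads_per_cell = 30, substitution_rate = 0.05,
                             ambient_barcode_rate = 0.2, seed = 13)
  a <- deconvolute_barcodes(dd$reads, dd$whitelist)
  perm <- withr::with_seed(1, sample(nrow(dd$reads)))
  b <- deconvolute_barcodes(dd$reads[perm, ], dd$whitelist)
  b <- b[match(a$read_id, b$read_id), ]
  rownames(b) <- NULL
  expect_equal(a, b)
  expect_equal(deconvolute_barcodes(dd$reads, dd$whitelist), a)
})

test_that("assignment labels agree with a brute-force distance oracle", {
  dd <- simulate_ddseq_reads(whitelist_size = 15, barcode_length = 8,
                             n_cells = 8, reads_per_cell = 25,
                             substitution_rate = 0.08,
                             ambient_barcode_rate = 0.25, seed = 17)
  a <- deconvolute_barcodes(dd$reads, dd$whitelist)
  matched <- unique(a$assigned_barcode[a$method %in% c("exact", "one_mismatch")])
  for (i in seq_len(nrow(a))) {
    o <- oracle_assign_read(dd$reads$barcode[i], dd$whitelist, matched)
    expect_equal(a$method[i], o$method, info = dd$reads$barcode[i])
    expect_equal(a$assigned_barcode[i], o$barcode, info = dd$reads$barcode[i])
  }
})

test_that("knee calling separates cells from ambient barcodes", {
  counts <- c(setNames(rep(1000, 10), paste0("cell", 1:10)),
              setNames(rep(1, 1000), paste0("amb", 1:1000)))
  expect_setequal(select_cell_barcodes(counts), paste0("cell", 1:10))
  expect_setequal(select_cell_barcodes(counts, override_cutoff = 500),
                  paste0("cell", 1:10))
  expect_error(select_cell_barcodes(numeric(0)), "empty")
  expect_error(select_cell_barcodes(c(a = 1, b = 2)), "at least 3")
})

test_that("automatic knee equals the exhaustive point-to-chord scan", {
  for (seed in 1:20) {
    counts <- withr::with_seed(seed, {
      n_cells <- sample(5:30, 1)
      n_amb <- sample(50:500, 1)
      c(setNames(round(stats::rlnorm(n_cells, log(500), 0.4)),
                 paste0("c", seq_len(n_cells))),
        setNames(sample(1:5, n_amb, replace = TRUE, prob = c(16, 8, 4, 2, 1)),
                 paste0("a", seq_len(n_amb))))
    })
    cnt <- sort(counts, decreasing = TRUE)
    got <- knee_rank(log10(seq_along(cnt)), log10(cnt))
    expect_equal(got, oracle_knee(counts), info = paste("seed", seed))
  }
})

test_that("UMI flattening counts distinct UMIs per cell and gene", {
  reads <- data.frame(
    read_id = sprintf("r%d", 1:6),
    cell = c("c1", "c1", "c1", "c1", "c2", "c2"),
    gene = c("gA", "gA", "gA", "gB", "gA", "gA"),
    umi = c("AAAA", "AAAA", "AAAT", "CCCC", "GGGG", "GGGG")
  )
  m <- flatten_umis(reads)
  expect_equal(as.numeric(m["gA", "c1"]), 2)   # AAAA collapsed, AAAT distinct
  expect_equal(as.numeric(m["gB", "c1"]), 1)
  expect_equal(as.numeric(m["gA", "c2"]), 1)
  expect_equal(as.matrix(m), oracle_flatten(reads), ignore_attr = TRUE)
})

test_that("flattening a demultiplexed run matches the set-based oracle", {
  dd <- simulate_ddseq_reads(whitelist_size = 12, n_cells = 6,
                             reads_per_cell = 40, substitution_rate = 0.01,
                             seed = 19, umi_length = 3)  # short UMIs force collisions
  asn <- deconvolute_barcodes(dd$reads, dd$whitelist)
  m <- flatten_umis(dd$reads, asn)
  keep <- !is.na(asn$assigned_barcode)
  df <- data.frame(cell = asn$assigned_barcode[keep],
                   gene = dd$reads$gene[keep], umi = dd$reads$umi[keep])
  expect_equal(as.matrix(m), oracle_flatten(df), ignore_attr = TRUE)
  expect_true(sum(m) < sum(keep))              # some PCR duplicates collapsed
})

test_that("poisson dedup reproduces the spec'd tail decisions", {
  st <- data.frame(unit_id = c("u1", "u2"), dup_count = c(3, 20),
                   adjacent_coverage = c(5, 2))
  out <- poisson_dedup(st)
  expect_equal(out$reduced_count[1], 3)        # tail ~0.875 >= 0.001
  expect_equal(out$reduced_count[2], 2)        # tail ~5e-13 < 0.001
  expect_equal(out$tail_p[1], oracle_poisson_tail(3, 5), tolerance = 1e-12)
  expect_equal(out$tail_p[2], oracle_poisson_tail(20, 2), tolerance = 1e-6)
  expect_error(poisson_dedup(data.frame(unit_id = "u", dup_count = -1,
                                        adjacent_coverage = 1)), "non-negative")
  expect_error(poisson_dedup(st, alpha = 0), "alpha")
})

test_that("dedup boundary at lambda = 2 matches brute-force pmf summation", {
  k_min_oracle <- which(sapply(1:50, function(k)
    oracle_poisson_tail(k, 2) < 0.001))[1]
  st <- data.frame(unit_id = paste0("u", 1:50), dup_count = 1:50,
                   adjacent_coverage = 2)
  out <- poisson_dedup(st)
  expect_equal(min(out$dup_count[out$flagged]), k_min_oracle)
  expect_false(out$flagged[out$dup_count == k_min_oracle - 1])
})

test_that("dedup never increases counts, is monotone, and vanishes as alpha -> 0", {
  st <- withr::with_seed(23, data.frame(
    unit_id = paste0("u", 1:200),
    dup_count = rpois(200, 4) + sample(0:30, 200, replace = TRUE),
    adjacent_coverage = runif(200, 0.5, 8)))
  out <- poisson_dedup(st)
  expect_true(all(out$reduced_count <= out$dup_count))
  tiny <- poisson_dedup(st, alpha = 1e-300)
  expect_equal(tiny$reduced_count, st$dup_count)
  # monotone in dup_count at fixed lambda
  lam <- 3
  ks <- 0:40
  fl <- poisson_dedup(data.frame(unit_id = paste0("k", ks), dup_count = ks,
                                 adjacent_coverage = lam))$flagged
  expect_true(all(diff(fl) >= 0))
})

test_that("adjacent coverage estimation averages the flanking window", {
  cov <- c(rep(2, 100), 50, rep(2, 100))
  est <- estimate_adjacent_coverage(cov, positions = 101, window = 10)
  expect_equal(est, 2)
  est2 <- estimate_adjacent_coverage(cov, positions = 100, window = 10)
  expect_gt(est2, 2)   # window covers the spike
})
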
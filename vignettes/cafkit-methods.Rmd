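---
title: "cafkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cafkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cafkit)
```

# Scope

`cafkit` packages the computational steps of a fibroblast-subtype single-cell
analysis as small, contract-tested functions: raw droplet-read processing
(barcode deconvolution, cell calling, UMI flattening), a Poisson
coverage-based duplicate filter for bulk libraries, single-cell
preprocessing, signature scoring and marker statistics, regulon-based
transcription factor (TF) activity, and pseudotime correlation analysis.
Upstream heavy machinery — read alignment, ambient-RNA removal, doublet
detection, batch integration, and trajectory inference itself — is out of
scope; those products (aligned gene labels, lineage assignments,
pseudotimes) are inputs here.

Because the package is meant to be testable without any external data, a
synthetic-data module generates every input with planted ground truth. All
statements below about recovery or calibration are the ones the test suite
and `scripts/acceptance.R` actually compute.

# Read processing

## Barcode deconvolution

Reads are assigned to whitelist barcodes in three stages with strict
precedence:

1. **exact** string match;
2. **one mismatch**: accepted only when exactly one whitelist barcode lies at
   Hamming distance 1. An `N` base can never match exactly and counts as a
   mismatch at its position.
3. **alignment rescue**: a still-unmatched read is compared by Levenshtein
   edit distance against the set of barcodes *observed* in stages 1–2, and
   accepted when a unique barcode is strictly closest within
   `rescue_max_edit` (default 2) edits.

Any tie at the deciding distance leaves the read unassigned. Two points were
genuinely open and are package decisions: the rescue stage aligns against
the observed matched-barcode set (not the whole whitelist), which reflects
reads from real cells whose barcodes have already been seen; and rescue uses
plain edit distance with a unique-best rule rather than an external
clustering tool, so the behavior has an exact, testable contract. Every
assignment is property-tested against a brute-force distance oracle.

## Knee-plot cell calling

`select_cell_barcodes()` reproduces manual cell calling when a count cutoff
is supplied. The automatic mode works on the log10(count) versus log10(rank)
curve: the knee is the rank with the largest perpendicular distance to the
chord joining the curve's endpoints, **taken on the upper (concave) side of
the chord**. The side matters: on a sharply bimodal curve the unsigned
maximum lands on the convex elbow at the top of the ambient cloud, which
would call every droplet a cell; the signed rule selects the shoulder where
cell-containing droplets end, which is what a knee plot is read for. All
barcodes with counts at or above the knee count are returned. Input should
be the raw per-barcode read abundances (cells plus ambient cloud); a
whitelist-filtered table with the ambient cloud removed has no knee to find.

## UMI flattening

`count(cell, gene)` is the number of *distinct* UMI strings observed for the
pair — exact-string identity, no UMI error correction (none was part of the
workflow being reproduced). With UMI length `L` the count saturates at
`4^L`; at typical depths this bias is negligible and is not corrected.

## Poisson duplicate filter

For each genomic unit carrying `k` exactly identical reads and adjacent
coverage `lambda`, the filter computes the upper tail `P(X >= k)` for
`X ~ Poisson(lambda)`. If this probability falls below `alpha = 0.001` the
unit's count is reduced to `max(1, round(lambda))` (never increased). Three
small interpretation choices are documented here: the tail is the upper one
(the filter targets implausibly *high* duplication); "reduced to the
adjacent coverage" rounds to the nearest integer with a floor of one read;
and `lambda` is taken as input, with `estimate_adjacent_coverage()` provided
as a helper (mean coverage in a configurable flanking window, excluding the
focal position). At `lambda = 2` the smallest flagged count is `k = 9`
(`P(X >= 9) ~ 4.0e-4 < 0.001`, `P(X >= 8) ~ 1.1e-3`), verified in the tests
by direct pmf summation.

# Single-cell preprocessing

* **QC**: cells need more than `min_genes = 1000` detected genes and less
  than `max_mito_pct = 10` percent mitochondrial UMIs (genes matching
  `^mt-`). These are the workflow's reference thresholds for deep real
  data; the simulated panels are much smaller, so the shipped demo config
  uses `min_genes = 200` with the same percent-mito rule.
* **Normalization**: `ln(1 + 1e4 * count / library_size)`.
* **Variable genes**: ranked by variance-stabilized standardized dispersion
  (a loess mean–variance trend on the raw counts predicts each gene's
  expected SD; standardized values are clipped at `sqrt(n_cells)` and their
  variance is the ranking statistic). The reference workflow fixes only the
  *number* (3,000); the ranking statistic is this package's choice of the
  field-standard vst approach. Ties break by gene identifier so selection is
  deterministic.
* **Covariate regression**: per-gene OLS with intercept (e.g. on cell-cycle
  scores computed with `signature_zscore()` from user-supplied gene lists);
  residuals are optionally centered/unit-scaled for PCA.
* **Component count**: the change at component *i* is
  `percent_variance[i-1] - percent_variance[i]` in percentage points;
  `select_pcs()` returns the largest *i* with change `> 0.1`, falling back
  to `min_pcs = 2`. Two readings were possible (consecutive difference vs
  relative/cumulative change); the consecutive-difference reading is
  implemented. A selected component must itself explain positive variance,
  which makes the rule invariant to padding with zero-variance components.
* **Clustering**: shared-nearest-neighbor graph (Jaccard overlap of
  20-neighborhoods, pruned below 1/15) partitioned by seeded Louvain
  modularity optimization at the requested resolution (0.1 coarse / 0.6
  fine in the reference workflow). The contract is the partition, not the
  algorithm brand; resolution semantics of graph libraries differ slightly,
  and the tests pin behavior on separated data, planted-truth recovery and
  determinism rather than on any specific community structure of one
  backend.

# Scoring

* **Signature Z-scores**: per gene `z = (x - mu)/sigma` across cells with
  the sample SD; a cell's score is the mean `z` over the signature, a
  cluster's score the mean over its cells. Zero-variance genes are dropped
  (the statistic is undefined for them), not scored as zero, with a warning.
* **Markers**: Wilcoxon rank-sum on normalized values, genes pre-filtered to
  at least 25% detection in one group, Bonferroni adjustment over tested
  genes; fold change is computed on the `expm1` scale with pseudocount 1 and
  the 1.5 threshold is on the natural ratio scale (log2 also reported).
  Test and adjustment follow the documented defaults of the marker function
  the thresholds come from, since only the thresholds were fixed upstream.
* **Pathway ranking**: a combined "significance and effect" ordering is
  implemented as the sum of the ascending q-value rank and the descending
  fold-change rank (only significant pathways, FC > 1 and adjusted p <
  0.05, enter). A literal arithmetic sum of a q value and a fold change is
  dimensionally incoherent, so the rank-sum reading is the default; the
  literal sum is available behind `method = "literal_sum"`.
* **TF activity (ulm)**: for each TF and cell, expression over all genes is
  regressed on the regulon weight vector with intercept; the activity is the
  slope t-statistic, `t = r * sqrt((n-2)/(1-r^2))`. Regulons need at least
  20 targets resolvable in the matrix. A perfect fit would give an infinite
  t; it is reported as a signed sentinel (1e6) with a warning. Differential
  activity centers and unit-scales activities per TF, then applies the
  marker machinery per cluster versus rest with no detection gate (activities
  are dense) and the mean difference as the effect size.
* **Pre-ranked GSEA**: weighted Kolmogorov–Smirnov running sum with weights
  `|statistic|`, gene-permutation null (`n_perm` random same-size sets),
  `p = (1 + #{null beyond ES in the matching tail}) / (n_perm + 1)` and
  `NES = ES / mean(|null ES| of the same sign)`; q values are
  Benjamini–Hochberg across sets. Because the null depends only on set
  size, null distributions are computed once per size. Sample permutation is
  impossible for a pre-ranked list, hence the gene-permutation null.

# Trajectory analysis

Lineages and pseudotimes are consumed as input. A per-lineage pseudotime
cutoff (a required analysis parameter, chosen by inspection in practice)
removes late cells; Pearson correlation of each feature against pseudotime
is computed with the t-based two-sided p value and Bonferroni adjustment
over tested features. Expression features must be detected (count > 0) in
at least 10% of the lineage's cells; TF-activity features are dense reals
and skip that gate. Selection keeps adjusted p < 0.05 and r > 0.25, ordered
by decreasing r — the ranked list handed to enrichment.

`naive_pseudotime()` (centroid minimum spanning tree with edge projection)
is demo plumbing only, shipped so examples run self-contained; it is
labeled non-conforming and is not a substitute for a dedicated
trajectory-inference method.

# The synthetic-data module

The generators emulate the statistical structure the pipeline assumes:

* **Counts**: negative binomial with variance `mu + mu^2 * phi`
  (`phi = 0.3` by default, a typical droplet-data value; `phi = 0` gives
  Poisson), log-normal library-size factors (`sigma = 0.3`), log-normal
  baseline gene means, and a mitochondrial block whose per-cell *expected*
  fraction is drawn uniformly from `mito_fraction_range` (default 1–8%,
  i.e. healthy cells under the 10% QC gate; realized fractions scatter
  around the target).
* **Subpopulations**: disjoint programs of `program_size` genes multiplied
  by `2^program_log2fc` (default 4-fold) within their subpopulation.
* **Trajectories**: per-lineage pseudotime spans [0, 1] exactly; dynamic
  genes rise monotonically as `2^(amplitude * logistic(10 (t - 0.5)))` — a
  sigmoid, deliberately not linear, so the Pearson-based selection is
  exercised on an imperfectly linear signal. Dynamic programs are planted
  among the upper half of baseline gene means: differentiation programs are
  expressed genes, and a near-silent gene cannot carry a detectable
  pseudotime signal.
* **Regulons**: target expression `weight * scale * activity + N(0, 1)`
  with weights in {−1, +1}, disjoint target sets, per-cell activities
  standard normal; `targets_per_tf` may vary per TF so the minimum-target
  filter is exercised.
* **Droplet reads**: whitelists are rejection-sampled to pairwise Hamming
  distance ≥ 3, which makes one-mismatch assignment well-posed (the real
  bead-barcode structure, possibly multi-block with linkers, is not public;
  the simulator treats the barcode as one contiguous string). Cell reads
  carry i.i.d. per-base substitutions; ambient reads carry random
  non-whitelist barcodes; UMIs are uniform; gene labels follow a 1/rank
  distribution.
* **Duplicate stacks**: background units Poisson around the adjacent
  coverage; artifact units inflated by a multiplier.

What the simulations do **not** model: ambient-RNA contamination profiles,
doublets, batch effects, base qualities, UMI errors, gene-length effects,
or realistic gene–gene correlation beyond the planted programs. Passing the
recovery tests therefore shows the statistics behave as designed under
their own assumptions — not that any particular biological dataset will be
recovered as cleanly.

# Study sizes and determinism

The recovery and calibration experiments run at desk scale, chosen as the
smallest sizes at which the tested effects are comfortably identifiable:
600 cells x 2,000 genes for subpopulation recovery (three planted programs,
4-fold effect), 300 cells per group for marker power, 200 cells for TF
recovery (5 regulons x 30 targets, signal scale 2), 800 cells x 800 genes
for the two-lineage dynamic-gene experiment (30 dynamic genes per lineage),
10,000 units for the duplicate-filter null, and 20 seeds for each null
calibration. Every generator and every stochastic step (clustering,
permutation GSEA) is a pure function of its seed; the acceptance script
derives all seeds from its `--seed` argument.

# Known limitations

* The Wilcoxon marker loop is plain R; it is fine at the package's intended
  fixture scale (thousands of genes) but not tuned for atlas-scale matrices.
* HVG selection densifies the count matrix; very large sparse matrices
  should be chunked upstream.
* The literal reading of the pathway ranking rule, the alternative rescue
  target set (whole whitelist), and relative/cumulative variants of the
  component-count rule are documented but not default behavior.
* Knee detection assumes a bimodal barcode abundance curve; on
  whitelist-filtered inputs without an ambient cloud the knee is undefined
  and the manual cutoff should be used.
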
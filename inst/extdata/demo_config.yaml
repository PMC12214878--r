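# Demonstration pipeline configuration: a two-lineage differentiation
# time-course with planted dynamic gene programs.
simulation:
  n_cells: 600
  n_genes: 1500
  n_lineages: 2
  n_dynamic_genes: 40
  program_log2fc: 2
  nb_dispersion: 0.3
  libsize_sigma: 0.3
  mito_fraction_range: [0.01, 0.08]
qc:
  min_genes: 200      # the simulated panel is small; real data uses 1000
  max_mito_pct: 10
hvg:
  n: 1000
pca:
  n_pcs: 30
  delta: 0.1
  min_pcs: 2
clustering:
  resolution: 0.6
  n_neighbors: 20
degs:
  min_pct: 0.25
  min_fc: 1.5
  alpha: 0.05
trajectory:
  pseudotime_cutoff: 1
  min_frac: 0.10
  alpha: 0.05
  min_r: 0.25
gsea:
  n_perm: 500
  min_set_size: 5
seed: 1
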
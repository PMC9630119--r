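seed: 7
simulate:
  counts:
    n_samples_per_group: 3
    cells_per_sample: 150
    n_genes: 300
    fold: 8
  sections:
    n_mice: 4
    n_sections_per_mouse: 3
    n_ref: 11
    n_target: 23
    assoc_prob: 0.5
    displacement_sigma: 8
    dapi_intensity: 0.001
    window: [600, 600]
qc:
  min_cells_per_gene: 3
  min_genes_per_cell: 50
  max_frac_mito: 0.1
states:
  tau: 0.5
composition:
  fdr: 0.4
proximity:
  radius: 20
  n_null_draws: 50
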
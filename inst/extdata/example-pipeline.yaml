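# Example configuration for `grnprune pipeline` / run_pipeline():
# a fully synthetic run at two distance thresholds.
thresholds: [1500, 2000]
correlation_thresholds: [0.25, 0.45, 0.65, 0.85]
k_max: 4
pruning:
  n_trees: 100
  relevance_fraction: 0.1
  seed: 1
simulate:
  n_tfs: 25
  n_genes: 150
  true_per_gene: 3
  decoys_per_gene: 12
  threshold_nt: 1500
  seed: 1
  n_samples: 400
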
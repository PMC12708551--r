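# Small end-to-end demo configuration: full workflow in well under a minute.
seed: 1
simulate_sc:
  n_cells_per_type: 150
  use_real_symbols: true
simulate_ihc:
  n_samples: 30
  indications: [HNSCC, BC, CRC]
markers:
  target: Mac_SPP1
  max_nonmac_fraction: 0.1
  max_other_mac_fraction: 0.5
  top_k: 5
pseudobulk:
  cells_per_sample: 300
  replicates: 3
scoring:
  log_transform: true
  quantile_normalize: false
ihc_cutoffs: [1, 5, 10, 25, 50]
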
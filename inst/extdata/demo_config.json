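{
  "seed": 99,
  "n_regions": 6,
  "clusters_per_region": 8,
  "households_per_cluster": 15,
  "factor_spatial_range": 1.5,
  "caseload_effect": 1.5
}
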
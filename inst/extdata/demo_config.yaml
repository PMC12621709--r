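# Demo pipeline configuration: the default synthetic cohort
# (11 AD + 9 control donors x 3 regions x 100 cells).
seed: 1
out_dir: demo_run
stages: [simulate, methylome, states, contacts, genome3d, loops]
sim:
  cells_per_sample: 100
  contacts_per_cell: 1200
methylome:
  # per-bin total-coverage window matched to the synthetic depth
  # (6,000 cells x mean coverage 6 per 100-kb bin)
  coverage_min: 1000
  coverage_max: 100000000
  top_k: 500
states: {}
contacts: {}
genome3d: {}
loops: {}
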
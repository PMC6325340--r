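# Example scaled-down run configuration for benthosurvey::read_run_config().
# Omitted fields keep the package defaults (the full study design).
seed: 7
n_perm: 199
effort_reps: 100
nmds_restarts: 5
survey:
  units_per_area: 8
  replicates_per_area: 3
community:
  n_species: 120
nodules:
  Flat:
    mean_cover: 10.1
  Ridge:
    mean_cover: 6.3
  Trough:
    mean_cover: 3.8
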
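# Example pipeline configuration. Unspecified fields take package defaults
# (see ?generation_config, ?matcher_config, ?pipeline_config).
generation:
  n_encounters: 4548
  prevalence_pwud: 0.5
  seed: 1
  race_dist: {minoritized: 0.348, white_nonhispanic: 0.652}
  sex_dist: {male: 0.624, female: 0.376}
  misspelling_rate: 0.15
  distractor_rate: 0.30
matcher:
  max_distance: 1
  min_token_len_for_fuzzy: 5
review:
  d_only_fraction: 0.10
  n_only_fraction: 0.35
output_dir: pwud_run
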
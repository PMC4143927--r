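# Bundled synthetic "toy cohort": a two-round family cohort of
# 600 + 300 individuals (150 nuclear families with four offspring,
# whole families assigned to one collection round), 5,000 autosomal
# markers and a 10-protein PEA panel. Heritabilities span 0.19-0.78,
# cis effects explain up to ~27% of trait variance on half the panel,
# the age effect reaches ~27%, medication indicators are rare, traits
# carry a collection-round batch shift and ~5% below-LOD censoring.
seed: 1
output_dir: toy_cohort_run
synthetic:
  n_families: 150
  offspring_per_family: 4
  n_singletons: 0
  cohort_split: 0.6666667
  n_markers: 5000
  n_proteins: 10
  n_medications: 8
  control_outlier_rate: 0.02
  h2_range: [0.19, 0.78]
  cis_fraction: 0.5
  cis_varexpl: [0.05, 0.27]
  age_effect_max: 0.27
  lod_censor_fraction: 0.05
  batch_effect: 0.2
thresholds:
  min_protein_obs: 200
  max_below_lod_fraction: 0.75
  alpha: 0.05
  min_mac: 3
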
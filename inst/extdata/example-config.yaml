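# Example pipeline configuration for `igrtmine run-all --config ...`.
# Unspecified fields keep package defaults.
seed: 1
cohort:
  n_patients: 150
  grid_shape: [48, 48, 36]
  spacing: [4, 4, 4]
  prescription_dose: 55
  n_fractions: 20
protocol:
  action_threshold: 5
  threshold_rule: per_axis
ibdm:
  n_perm: 500
  region_fraction: 0.8
  sigma_mm: 2
  qa_tolerance_mm: 10
  coverage: 0.9
survival:
  merge_lowest: 3
  cv_folds: 5
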
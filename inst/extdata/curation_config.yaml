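# Design-curation policy: threshold applied to AUC/C-index values as
# printed, a separate threshold for variance-explained (R2) metrics,
# below-threshold exceptions, and duplicate overrides expressing whole-study
# judgement (UKB-validated sources preferred over higher-scoring FINRISK
# duplicates for these phenotypes).
performance_threshold: 0.60
metric_thresholds:
  R2: 0.10
exceptions:
  - Ischaemic stroke
duplicate_overrides:
  Breast cancer: PGS000015
  Coronary Artery Disease: PGS000013
  Type 2 diabetes: PGS000014
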
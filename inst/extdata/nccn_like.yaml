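# Default synthetic corpus: 67 two-arm RCTs in 9 treatment categories,
# shaped like the trial corpus cited by clinical guidelines for rectal
# cancer. All records are SYNTHETIC; parameters are tuned to published
# corpus-shape facts (per-category study counts, the median/IQR of trial
# sizes, the median/IQR of loss to follow-up), not to any real trial.
#
# arm_size_range:           per-arm size, drawn log-uniformly
# control_event_rate_range: control-arm event probability, uniform
# odds_ratio_range:         intervention odds ratio, log-uniform
# ltfu_rate_range:          fraction of randomized patients lost, uniform
# significance_screen:      redraw until the Fisher exact p < alpha

alpha: 0.05
seed: 20230725
max_resamples: 5000

categories:
  - treatment_category: "neoadjuvant chemotherapy"
    n_studies: 10
    arm_size_range: [30, 120]
    control_event_rate_range: [0.30, 0.50]
    odds_ratio_range: [1.8, 3.0]
    ltfu_rate_range: [0.0, 0.004]
    significance_screen: true
  - treatment_category: "neoadjuvant radiotherapy"
    n_studies: 5
    arm_size_range: [80, 260]
    control_event_rate_range: [0.15, 0.35]
    odds_ratio_range: [1.8, 2.8]
    ltfu_rate_range: [0.0, 0.015]
    significance_screen: true
  - treatment_category: "neoadjuvant chemoradiation"
    n_studies: 6
    arm_size_range: [45, 180]
    control_event_rate_range: [0.30, 0.50]
    odds_ratio_range: [1.6, 2.4]
    ltfu_rate_range: [0.02, 0.06]
    significance_screen: true
  - treatment_category: "neoadjuvant immunotherapy"
    n_studies: 3
    arm_size_range: [18, 45]
    control_event_rate_range: [0.20, 0.40]
    odds_ratio_range: [1.2, 2.2]
    ltfu_rate_range: [0.05, 0.12]
    significance_screen: true
  - treatment_category: "surgical intervention"
    n_studies: 9
    arm_size_range: [90, 270]
    control_event_rate_range: [0.20, 0.40]
    odds_ratio_range: [2.2, 3.5]
    ltfu_rate_range: [0.01, 0.04]
    significance_screen: true
  - treatment_category: "metastatic liver disease treatment"
    n_studies: 19
    arm_size_range: [15, 60]
    control_event_rate_range: [0.25, 0.50]
    odds_ratio_range: [1.8, 3.5]
    ltfu_rate_range: [0.0, 0.01]
    significance_screen: true
  - treatment_category: "adjuvant chemotherapy"
    n_studies: 5
    arm_size_range: [60, 200]
    control_event_rate_range: [0.25, 0.45]
    odds_ratio_range: [1.9, 3.0]
    ltfu_rate_range: [0.0, 0.012]
    significance_screen: true
  - treatment_category: "adjuvant immunotherapy"
    n_studies: 2
    arm_size_range: [60, 180]
    control_event_rate_range: [0.25, 0.45]
    odds_ratio_range: [2.0, 3.0]
    ltfu_rate_range: [0.02, 0.06]
    significance_screen: true
  - treatment_category: "follow-up and chemoprevention"
    n_studies: 8
    arm_size_range: [45, 190]
    control_event_rate_range: [0.20, 0.40]
    odds_ratio_range: [1.7, 2.6]
    ltfu_rate_range: [0.06, 0.18]
    significance_screen: true
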
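n_samples: 120
n_features: 300
n_groups: 3
group_proportions: [0.45, 0.245, 0.305]
n_modules: 25
module_size_range: [3, 8]
within_module_corr: 0.8
n_informative_modules: 8
effect_size: 2.0
technical_cv: 0.088
hazard_scale_per_group: [0.10, 0.15, 0.22]
censoring_rate: 0.02
followup_horizon: 14
seed: 42
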
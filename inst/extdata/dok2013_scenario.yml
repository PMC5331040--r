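baseline_fraction: 0.5
dispersion_logit: 0.9
root_mean: -13.3
root_sd: 0.5
eom_mean: -29.3
eom_sd: 0.3
sigma_instrument: 0.2
n_missing: 5
mass_ratio_fine_to_coarse: 1.82
seed: 1
effect_treatment_BIOORG1: -0.2399398
effect_treatment_BIOORG2: -0.0485563
effect_treatment_CONFYM2: 0.3006027
effect_depth_D1: -0.3815395
effect_depth_D3: 0.4055535
effect_position_inter_row: -1.0647769
effect_size_class_coarse: 1.1587812
effect_size_class_fine: -0.3787546
effect_exclusion_yes: 1.1587812
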
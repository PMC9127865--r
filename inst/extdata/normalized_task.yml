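# Normalized two-context task: sigma = 1, means on a 0-10 scale.
# The 0-100 point task with sigma = 13 corresponds to beta values
# thirteen times smaller than on this scale.
mu:
- 7.0
- 5.0
- 7.0
- 3.0
sigma:
- 1.0
- 1.0
- 1.0
- 1.0
min_trials: 100
max_trials: 300
stop_tolerance: 1.0
transfer_repeats: 4
estimation_repeats: 4
regime: partial
q0: 0.0
estimate_noise_sd: 1.0
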
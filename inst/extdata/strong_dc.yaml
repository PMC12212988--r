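# strong developmental-constraints regime: 0.5 per sd of e0, noise sd 0.5
n_females: 300
obs_per_female: 10
n_groups: 8
gamma:
  intercept: 0.5
  e0: 0.5
noise_sd: 0.5
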
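# all environment effects zero: size / type-I-error studies
n_females: 300
obs_per_female: 10
n_groups: 8
gamma:
  intercept: 0.5
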
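# Example run configuration. Omitted keys keep the package defaults.
fc_affected: 1.5
fc_unaffected: 1.2
r2_high: 0.7
r2_low: 0.3
noise_cv: 0.2
dialect: generic
seed: 42
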
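# Example simulation configuration.
replicates: 10
timepoints: 20
noise_pct: 5
exponent: 0.15
decay: true
seed: 7
perturbations:
  - node: A
    mode: inhibit
    release_step: 1
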
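# Three-node activation chain; pair with perturbation_demo_def.sif.
# Intended use: inhibit A externally, releasing after time point 1.
A activates B
B activates C
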
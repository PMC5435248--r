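# Unperturbed twin of perturbation_demo_abc.sif.
D activates E
E activates F
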
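# Seven-node strength demonstration: one source with graded edges.
A weakly_inhibits B
A inhibits C
A strongly_inhibits D
A weakly_activates E
A activates F
A strongly_activates G
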
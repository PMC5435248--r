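# EGFR signaling example network (synthetic).
# Topology after published EGF-stimulation phosphoproteomics of HeLa cells.
# Only the EGFR->STAM2 (weak) and EGFR->Shc1 (strong) strengths reflect the
# observed activation dynamics; the remaining strengths are illustrative
# defaults ('activates'/'inhibits' at standard strength) and should be
# edited to match any experimental data available for the system.
EGFR weakly_activates STAM2
EGFR strongly_activates Shc1
EGFR activates Grb2
Shc1 activates Grb2
Grb2 activates SOS1
SOS1 activates ERK
EGFR inhibits CytochromeC
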
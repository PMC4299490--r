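cell_type	frequency
HSCe	0.08
MLP	0.06
CMP	0.22
MEP	0.18
GMP	0.20
EryB	0.06
Mega	0.03
Neut	0.03
Baso	0.02
Eos	0.02
Mono	0.06
PreB	0.04
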
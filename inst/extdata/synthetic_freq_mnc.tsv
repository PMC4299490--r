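cell_type	frequency
HSCe	0.0005
MLP	0.001
CMP	0.002
MEP	0.002
GMP	0.002
EryB	0.05
Mega	0.005
Neut	0.55
Baso	0.01
Eos	0.03
Mono	0.20
PreB	0.02
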
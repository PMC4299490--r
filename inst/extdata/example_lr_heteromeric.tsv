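ligand	receptor	confidence	heteromericGroup
IL6	IL6R	0.9	IL6_complex
IL6	IL6ST	0.9	IL6_complex
KITLG	KIT	1.0	NA
THPO	MPL	1.0	NA
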
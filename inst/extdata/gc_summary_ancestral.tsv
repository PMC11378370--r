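genome	region	n	gc_mean	gc_sd
A1	S0+	274	0.333	0.084
A1	S1	115	0.383	0.055
A1	S2	144	0.377	0.089
A1	intergene	5283	0.309	0.055
A2	S0+	259	0.337	0.089
A2	S1	112	0.381	0.055
A2	S2	142	0.368	0.071
A2	intergene	5304	0.299	0.063
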
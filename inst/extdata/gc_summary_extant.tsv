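region	n	gc_mean	gc_sd
S0+	448	0.373	0.105
S1	142	0.407	0.071
S2	172	0.389	0.077
S3	136	0.402	0.071
S4	301	0.400	0.071
annotated	6459	0.393	0.071
intergene	6006	0.333	0.055
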
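haplotype_id	nomenclature	variant_tag	KIR2DL1	KIR2DL2	KIR2DL3	KIR2DL4	KIR2DL5	KIR2DS1	KIR2DS2	KIR2DS3	KIR2DS4	KIR2DS5	KIR3DL1	KIR3DL2	KIR3DL3	KIR3DS1	KIR2DP1	KIR3DP1
1	cA01~tA01		1	0	1	1	0	0	0	0	1	0	1	1	1	0	1	1
3	cA01~tB01		1	0	1	1	1	1	0	0	0	1	0	1	1	1	1	1
4	cB02~tA01		0	1	0	1	0	0	1	0	1	0	1	1	1	0	0	1
5	cB01~tA01		1	1	0	1	1	0	1	1	1	0	1	1	1	0	1	1
7	cB02~tB01		0	1	0	1	1	1	1	0	0	1	0	1	1	1	0	1
49			1	1	0	1	0	0	1	0	1	0	2	1	1	0	1	1
51			1	1	0	1	0	0	1	0	1	0	1	1	1	0	1	1
60			1	0	1	1	0	0	0	0	1	0	1	1	0	0	1	1
98	cB03~tA01	_2DS3	1	1	0	1	0	0	1	1	1	0	1	1	1	0	1	1
99	cB03~tA01	_2DS5	1	1	0	1	0	0	1	0	1	1	1	1	1	0	1	1
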
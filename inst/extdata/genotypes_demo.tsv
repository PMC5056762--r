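sample_id	population	KIR2DL1	KIR2DL2	KIR2DL3	KIR2DL4	KIR2DL5	KIR2DS1	KIR2DS2	KIR2DS3	KIR2DS4	KIR2DS5	KIR3DL1	KIR3DL2	KIR3DL3	KIR3DS1	KIR2DP1	KIR3DP1
S00001	AFA	Y	Y	Y	2	Y	Y	Y	Y	Y	Y	Y	2	2	Y	Y	2
S00002	AFA	Y	N	Y	2	N	N	N	N	Y	N	Y	2	2	N	Y	2
S00003	EUR	Y	N	Y	2	N	N	N	N	Y	N	Y	2	2	N		2
S00004	AFA	Y	N	Y	2	N	N	N	N	Y	N	Y	2	1	N	Y	2
S00005	AFA	Y	Y	N	2	Y	Y	Y	Y	Y	Y	Y	2	2	Y	Y	2
S00006	AFA	Y	Y	Y	2	N	N	Y	N	Y	N	Y	2	2	N	Y	2
S00007	EUR	Y	Y	Y	2	Y	Y	Y	Y	Y	Y	Y	2	2	Y	Y	
S00008	EUR	Y	Y	N	2	Y	N	Y	Y	Y	N	Y	2	2	N	Y	2
S00009	EUR	Y	Y	Y	2	N	N	Y	N	Y	N	Y	2	2	N	Y	2
S00010	AFA	Y	N	Y	2	Y	Y	N	N	Y	Y	Y	2	1	Y	Y	2
S00011	EUR	N	Y	N	2	N	N	Y	N	Y	N	Y	2	2	N	N	2
S00012	AFA	N	Y	N	2	Y	Y	Y	N	Y	Y	Y	2	2	Y	N	2
S00013	EUR	Y	Y	Y	2	Y	Y	Y	N	Y	Y	Y	2	2	Y	Y	2
S00014	EUR	Y	Y	Y	2	N	N	Y	N	Y	N	Y	2	2	N	Y	2
S00015	EUR	Y	N	Y	2	N	N	N	N	Y	N	Y	2	2	N	Y	2
S00016	EUR	Y	Y	N	2	N	N	Y	N	Y	N	Y	2	2	N	Y	2
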
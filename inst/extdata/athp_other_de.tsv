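feature_id	refseq	fold_change_abs	direction	p_value	contrast
Pnkd	NM_025580	4.88	up	0.01	SC24W_vs_B8W
App	NM_001198826	2.32	up	0.03	siCD40_24W_vs_SC24W
Cyth2	NM_011181	2.97	up	0.0001	siCD40_24W_vs_SC24W
Cyth2	NM_001112701	2.70	up	0.01	siCD40_24W_vs_SC24W
Gm3286	NM_001122678	2.15	up	0.010	siCD40_24W_vs_SC24W
Macrod2	NM_028387	2.41	up	0.02	siCD40_24W_vs_SC24W
Macrod2	NM_001013802	2.43	up	0.03	siCD40_24W_vs_SC24W
Sgk1	NM_001161845	2.94	up	0.02	siCD40_24W_vs_SC24W
Sgk1	NM_001161847	2.21	up	0.02	siCD40_24W_vs_SC24W
Trmt2a	NM_001080999	3.16	up	0.01	siCD40_24W_vs_SC24W
Trmt2a	NM_001195205	4.94	up	0.01	siCD40_24W_vs_SC24W
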
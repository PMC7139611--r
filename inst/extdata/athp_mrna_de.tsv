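feature_id	refseq	fold_change_abs	direction	p_value	contrast
Atp2a2	NM_001110140	2.50	down	0.011	SC24W_vs_B8W
Ccr7	NM_007719	13.63	down	0.019	SC24W_vs_B8W
Dapk1	NM_029653	3.90	down	0.002	SC24W_vs_B8W
Egfr	NM_007912	4.43	down	0.035	SC24W_vs_B8W
Fos	NM_010234	2.67	down	0.001	SC24W_vs_B8W
Foxo1	NM_019739	4.16	down	0.02	SC24W_vs_B8W
Gata4	NM_008092	3.63	down	0.001	SC24W_vs_B8W
Kcnh3	NM_010601	3.44	down	0.022	SC24W_vs_B8W
Map2k1	NM_008927	2.55	down	0.02	SC24W_vs_B8W
Mapk1	NM_011949	11.98	down	0.02	SC24W_vs_B8W
Mapk9	NM_001163671	2.85	down	0.005	SC24W_vs_B8W
Mgat3	NM_010795	27.02	down	0.005	SC24W_vs_B8W
Rnf7	NM_011279	33.12	down	0.02	SC24W_vs_B8W
Vkorc1l1	NM_001001327	3.95	down	0.03	SC24W_vs_B8W
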
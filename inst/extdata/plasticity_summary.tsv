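stress_a	stress_b	gene_pairings	plastic_pairs	plastic_pct	mean_false_positives	fdr	delta_r_cutoff
drought	salt	276950	27916	10.1	1368.1	0.049	0.97
drought	cold	16665	2921	17.5	144.9	0.049	0.96
drought	heat	70434	4890	6.9	239.9	0.049	0.98
salt	heat	26562	241	0.9	11.9	0.049	1.35
salt	cold	8132	2027	24.9	94.8	0.047	0.94
heat	cold	522	128	24.5	6.0	0.047	0.88
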
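gene_label	ranking	n_vectors_total	pct_transforming	repression_fold_g1	repression_fold_g2	induction_fold_anchor_loss
MK3	1092	14	78	1.8	2.1	2.0
p21	477	9	53	2.2	2.2	2.6
Tug1	352	16	22	1.4	1.7	1.4
Actr2	203	7	29	0.8	1.0	1.0
Ado	184	8	23	1.3	0.8	1.1
Lrrc8a	176	4	44	0.8	0.7	0.9
Gabarap	176	4	44	1.8	1.3	1.9
Mir34a	176	8	22	2.2	2.1	2.1
GabrB3	156	6	26	2.1	3.5	4.3
Arpc1b	145	5	29	1.1	0.9	1.0
Moesin	132	6	22	0.8	0.9	0.6
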
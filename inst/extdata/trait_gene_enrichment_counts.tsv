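trait	k	n	K	N	reference_fold	reconstructable
Height	118	414	2094	8277	1.41	FALSE
CAD_extended	90	239	2094	8371	1.51	TRUE
CAD_extended_no_lipid	78	204	2094	8357	1.53	TRUE
Inflammatory_bowel_disease	85	232	2094	8277	1.45	TRUE
Platelet	32	75	2094	8277	1.69	TRUE
Aneurysm	16	35	2094	8277	1.81	TRUE
Systemic_lupus_erythematosis	25	64	2094	8277	1.54	TRUE
CAD	49	145	2094	8277	1.34	TRUE
Migraine	11	23	2094	8277	1.89	TRUE
CAD_no_lipid	42	124	2094	8277	1.34	TRUE
Breast_cancer	38	131	2094	8277	1.15	TRUE
Schizophrenia	50	193	2094	8277	1.02	TRUE
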
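dataset_id	size_orig	leaves_orig	accuracy_orig	size_prot	leaves_prot	accuracy_prot
Abalone	2312	1183	21.97	2312	1183	21.97
Acute inflammations	5	3	100.00	5	3	100.00
Arrhythmia	99	50	71.43	99	50	71.43
Audiology (standardized)	54	32	83.12	54	32	83.12
Breast cancer	6	4	68.04	6	4	68.04
Breast cancer Wisconsin (original)	27	14	95.38	27	14	95.38
Breast tissue	29	15	47.22	29	15	47.22
Cardiotocography	19	14	98.34	33	25	98.34
Contraceptive method choice	263	157	55.29	263	157	55.29
Covertype	29793	14897	93.59	29793	14897	93.59
Dermatology	41	31	92.74	41	31	92.74
Echocardiogram	9	5	70.37	9	5	70.37
Ecoli	43	22	78.95	43	22	78.95
Haberman's survival	5	3	75.96	5	3	75.96
Hepatitis	21	11	79.25	21	11	79.25
Horse colic	29	18	68.55	29	18	68.55
Iris	9	5	96.08	9	5	96.08
Lung cancer	16	10	63.64	16	10	63.64
Lymphography	34	21	78.00	34	21	78.00
Mammographic mass	15	12	82.26	15	12	82.26
Mushroom	30	25	100.00	30	25	100.00
Pima Indians diabetes	39	20	76.25	39	20	76.25
Post-operative patient	1	1	70.97	1	1	70.97
Primary tumor	88	47	39.13	88	47	39.13
Seeds	15	8	97.18	15	8	97.18
Soybean (large)	93	61	90.52	93	61	90.52
Spectf heart	17	9	66.67	17	9	66.67
Statlog (heart)	45	27	76.09	45	27	76.09
Yeast	369	185	58.81	369	185	58.81
Zoo	17	9	94.12	17	9	94.12
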
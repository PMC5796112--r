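model_id	specificity	n_hits	pareto	energy	sterics	hbond	mol_qry
model 01	3.458	6	0	10.79	203.10	107.90	2.29
model 02	3.456	6	0	4.52	193.60	101.10	2.90
model 03	3.458	6	0	13.70	203.10	107.90	2.29
model 11	3.458	6	0	14.14	200.50	108.90	2.29
model 13	3.454	6	0	16.61	203.30	107.40	2.15
model 15	3.451	6	0	3.73	187.10	107.70	0.66
model 16	3.452	6	0	6.98	188.50	102.70	2.29
model 17	3.452	6	0	8.95	195.10	99.40	2.29
model 18	3.452	6	0	10.72	187.40	104.70	2.29
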
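compound_id	ki_nM	total_score
CHEMBL33567	61	6.3650
CHEMBL277475	210	6.9249
CHEMBL89000	1700	6.0272
CHEMBL280563	3400	5.9511
CHEMBL88999	7300	5.1538
BDBM17657	9500	4.6927
CHEMBL8759	12,000	4.1048
CHEMBL330097	15,000	3.6829
CHEMBL34453	45,000	5.9186
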
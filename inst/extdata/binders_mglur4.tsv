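compound_id	ki_nM	total_score
CHEMBL33567	910	7.2647
CHEMBL277475	5200	7.4445
CHEMBL329236	8800	6.6985
CHEMBL89000	21,000	6.6781
CHEMBL90501	23,000	6.1632
CHEMBL88612	26,000	4.3929
CHEMBL41221	470,000	5.6421
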
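compound_id	ki_nM	total_score
CHEMBL33567	175,000	6.8675
CHEMBL277475	185,000	6.4943
BDBM17657	5,400,000	5.215
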
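name	sequence	class
CD56	CTGACTTCACACGAG	marker
CD155	ACCTCTTTCATCAGG	marker
CD29	CACGCGCTCTGTGTG	marker
CD4	TAATGAAAGCACTGA	marker
CD45	TCCACTGGCTTCATT	marker
CD28	GTCCCTGTACATTCG	marker
IgG1	TCATTGCGGACTCAC	isotype_control
HT1	CAGTACAATACTTTC	hashtag
HT2	ATGGCCACGCAACGC	hashtag
HT3	TCAATCATATTAGAG	hashtag
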
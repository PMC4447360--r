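label	k	n	K	N	reference_fold
Adipose	548	12362	1488	81223	2.42
Liver	324	8504	1488	81223	2.08
Blood	381	11576	1488	81223	1.80
Brain	171	3924	1488	81223	2.38
HAEC	159	4889	1488	81223	1.78
Regulatory_cat1	1354	34338	4907	256788	2.06
Regulatory_cat2	1252	46217	4907	256788	1.42
Regulatory_cat3	619	30429	4907	256788	1.06
Regulatory_cat4	2413	95580	4907	256788	1.32
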
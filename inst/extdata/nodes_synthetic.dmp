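1	|	1	|	no rank	|
131567	|	1	|	no rank	|
2	|	131567	|	superkingdom	|
2157	|	131567	|	superkingdom	|
2759	|	131567	|	superkingdom	|
10239	|	1	|	superkingdom	|
33154	|	2759	|	clade	|
4751	|	33154	|	kingdom	|
33208	|	2759	|	kingdom	|
9605	|	33208	|	genus	|
9606	|	9605	|	species	|
543	|	2	|	family	|
561	|	543	|	genus	|
562	|	561	|	species	|
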
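1	|	1	|	no rank	|
131567	|	1	|	no rank	|
2	|	131567	|	superkingdom	|
1224	|	2	|	phylum	|
1236	|	1224	|	class	|
91347	|	1236	|	order	|
543	|	91347	|	family	|
561	|	543	|	genus	|
562	|	561	|	species	|
83333	|	562	|	no rank	|
620	|	543	|	genus	|
622	|	620	|	species	|
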
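1	|	root	|		|	scientific name	|
131567	|	cellular organisms	|		|	scientific name	|
2	|	Bacteria	|		|	scientific name	|
2	|	eubacteria	|		|	synonym	|
1224	|	Proteobacteria	|		|	scientific name	|
1236	|	Gammaproteobacteria	|		|	scientific name	|
91347	|	Enterobacterales	|		|	scientific name	|
543	|	Enterobacteriaceae	|		|	scientific name	|
561	|	Escherichia	|		|	scientific name	|
562	|	Escherichia coli	|		|	scientific name	|
83333	|	Escherichia coli K-12	|		|	scientific name	|
620	|	Shigella	|		|	scientific name	|
622	|	Shigella dysenteriae	|		|	scientific name	|
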
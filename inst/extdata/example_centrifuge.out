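readID	seqID	taxID	score	2ndBestScore	hitLength	queryLength	numMatches
read1	seq_562	562	120	0	100	100	1
read2	seq_562	562	80	0	80	100	1
read3	seq_562	562	60	0	60	100	1
read4	seq_622	622	200	0	150	150	1
read5	seq_83333	83333	90	0	90	100	1
read6	unclassified	0	0	0	0	100	1
read7	seq_666	666	110	0	100	100	1
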
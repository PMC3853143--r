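part_id	role	level	genes
R1	RBS	1	*
R2	RBS	2	*
R3	RBS	3	*
R4	RBS	4	*
R5	RBS	5	*
T1	PDT	1	*
T2	PDT	2	*
T3	PDT	3	*
T4	PDT	4	*
T5	PDT	5	*
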
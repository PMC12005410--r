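target_id	position	base	count
pRNA_6S1	5	G	1
pRNA_6S1	6	G	9
pRNA_6S1	7	T	903
pRNA_6S1	9	A	2422
pRNA_6S1	10	A	1491
pRNA_6S1	11	A	926
pRNA_6S1	12	A	899
pRNA_6S1	14	T	647
pRNA_6S1	15	A	13
pRNA_6S1	16	G	2
pRNA_6S1	18	T	1
pRNA_6S1	19	G	6
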
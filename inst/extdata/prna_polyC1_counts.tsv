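target_id	position	base	count
pRNA_6S1	6	G	3
pRNA_6S1	7	T	200
pRNA_6S1	9	A	497
pRNA_6S1	10	A	368
pRNA_6S1	11	A	253
pRNA_6S1	12	A	98
pRNA_6S1	14	T	109
pRNA_6S1	15	A	2
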
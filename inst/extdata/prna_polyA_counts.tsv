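target_id	position	base	count
pRNA_6S1	5	G	4
pRNA_6S1	6	G	2
pRNA_6S1	7	T	4
pRNA_6S1	8	C	488
pRNA_6S1	13	C	48
pRNA_6S1	14	T	35
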
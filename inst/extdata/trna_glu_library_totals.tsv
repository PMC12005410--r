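library	total_mapped
adapter	212
polyA	12038
polyC1	1396
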
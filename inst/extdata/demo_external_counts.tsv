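gene_id	deceased_count	alive_count
g042	14	2
g007	3	5
g013	0	1
g058	6	7
g090	1	0
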
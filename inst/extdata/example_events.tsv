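onset_s	tier	label	word_index
0	word	ba	1
0	phoneme	b	1
0.25	phoneme	a	1
0.5	word	da	2
0.5	phoneme	d	2
0.75	phoneme	a	2
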
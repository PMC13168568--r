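word	frequency	phonemes
ba	20	b a
bi	10	b i
da	5	d a
badi	2	b a d i
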
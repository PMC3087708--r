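predicted	RELIABLE	REMAPPED_RETIRED	REMAPPED_WRONG_INSERT	UNRELIABLE
Green	187	56	20	23
Yellow	78	80	4	24
Red	4	16	1	3
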
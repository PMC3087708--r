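category	n	sequenced	remapped
RELIABLE	15979	286	2702
MARGINAL	249	186	122
UNRELIABLE	28	24	27
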
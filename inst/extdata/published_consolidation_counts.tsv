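tissue	n_consistent	n_consistent_conserved
brain	5426	5138
liver	1851	1252
muscle	1361	1054
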
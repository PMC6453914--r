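tissue	n_detected	n_up	n_down
brain	24267	104	91
liver	20943	1502	1704
muscle	22705	1505	1118
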
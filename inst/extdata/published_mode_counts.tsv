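tissue	group	mode	n
brain	MC	conserved	8754
brain	MC	additive	847
brain	MC	cor_dominant	2283
brain	MC	wl_dominant	1497
brain	MC	over_dominant	1026
brain	MC	under_dominant	910
brain	FC	conserved	8688
brain	FC	additive	822
brain	FC	cor_dominant	2341
brain	FC	wl_dominant	1461
brain	FC	over_dominant	1110
brain	FC	under_dominant	946
brain	MR	conserved	8389
brain	MR	additive	882
brain	MR	cor_dominant	2033
brain	MR	wl_dominant	1969
brain	MR	over_dominant	1091
brain	MR	under_dominant	961
brain	FR	conserved	7733
brain	FR	additive	715
brain	FR	cor_dominant	2641
brain	FR	wl_dominant	1470
brain	FR	over_dominant	1379
brain	FR	under_dominant	1286
liver	MC	conserved	4317
liver	MC	additive	1306
liver	MC	cor_dominant	3083
liver	MC	wl_dominant	2504
liver	MC	over_dominant	1720
liver	MC	under_dominant	1230
liver	FC	conserved	4195
liver	FC	additive	1508
liver	FC	cor_dominant	2795
liver	FC	wl_dominant	2757
liver	FC	over_dominant	1615
liver	FC	under_dominant	1261
liver	MR	conserved	3883
liver	MR	additive	1292
liver	MR	cor_dominant	2477
liver	MR	wl_dominant	3069
liver	MR	over_dominant	2318
liver	MR	under_dominant	1146
liver	FR	conserved	4393
liver	FR	additive	1305
liver	FR	cor_dominant	2352
liver	FR	wl_dominant	2651
liver	FR	over_dominant	1632
liver	FR	under_dominant	1546
muscle	MC	conserved	3900
muscle	MC	additive	961
muscle	MC	cor_dominant	3926
muscle	MC	wl_dominant	1775
muscle	MC	over_dominant	2264
muscle	MC	under_dominant	1946
muscle	FC	conserved	4015
muscle	FC	additive	1066
muscle	FC	cor_dominant	3626
muscle	FC	wl_dominant	1946
muscle	FC	over_dominant	2211
muscle	FC	under_dominant	1889
muscle	MR	conserved	5185
muscle	MR	additive	1169
muscle	MR	cor_dominant	1742
muscle	MR	wl_dominant	4136
muscle	MR	over_dominant	979
muscle	MR	under_dominant	1590
muscle	FR	conserved	3772
muscle	FR	additive	1090
muscle	FR	cor_dominant	2864
muscle	FR	wl_dominant	2953
muscle	FR	over_dominant	1408
muscle	FR	under_dominant	2609
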
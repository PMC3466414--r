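sample_set	pool	treatment	input_ng	cycles	reconditioned	replicate	barcode	reads
isolate	1	cyc15A	10	15	FALSE	A	CGACA	4306
isolate	1	cyc15B	10	15	FALSE	B	CATAG	1626
isolate	1	cyc15C	10	15	FALSE	C	ATGTA	7582
isolate	1	cyc18A	1	18	FALSE	A	CGTGT	8072
isolate	1	cyc18B	1	18	FALSE	B	ACGTG	11889
isolate	1	cyc18C	1	18	FALSE	C	TGAGT	12739
isolate	1	cyc20A	0.1	20	FALSE	A	CTCTA	8729
isolate	1	cyc20B	0.1	20	FALSE	B	ACTCT	3
isolate	1	cyc20C	0.1	20	FALSE	C	TGCTG	5186
isolate	1	cyc25A	0.01	25	FALSE	A	CTATG	8722
isolate	1	cyc25B	0.01	25	FALSE	B	AGCAT	8006
isolate	1	cyc25C	0.01	25	FALSE	C	TCGCA	6091
isolate	1	cyc30A	0.001	30	FALSE	A	CTGAG	7250
isolate	1	cyc30B	0.001	30	FALSE	B	ATCAG	8201
isolate	1	cyc30C	0.001	30	FALSE	C	TCATA	10992
isolate	2	cyc15rA	10	15	TRUE	A	CGACA	1287
isolate	2	cyc15rB	10	15	TRUE	B	CATAG	2088
isolate	2	cyc15rC	10	15	TRUE	C	ATGTA	1710
isolate	2	cyc18rA	1	18	TRUE	A	CGTGT	1183
isolate	2	cyc18rB	1	18	TRUE	B	ACGTG	436
isolate	2	cyc18rC	1	18	TRUE	C	TGAGT	900
isolate	2	cyc20rA	0.1	20	TRUE	A	CTCTA	4431
isolate	2	cyc20rB	0.1	20	TRUE	B	ACTCT	4
isolate	2	cyc20rC	0.1	20	TRUE	C	TGCTG	1194
isolate	2	cyc25rA	0.01	25	TRUE	A	CTATG	2768
isolate	2	cyc25rB	0.01	25	TRUE	B	AGCAT	1157
isolate	2	cyc25rC	0.01	25	TRUE	C	TCGCA	1527
isolate	2	cyc30rA	0.001	30	TRUE	A	CTGAG	1775
isolate	2	cyc30rB	0.001	30	TRUE	B	ATCAG	5195
isolate	2	cyc30rC	0.001	30	TRUE	C	TCATA	1252
isolate	2	unamp	NA	0	FALSE	NA	NA	30279
community	1	B2cyc15A	10	15	FALSE	A	CGACA	222421
community	1	B2cyc25A	0.1	25	FALSE	A	CAGAT	212093
community	1	B2cyc15rA	10	15	TRUE	A	ACGTG	119144
community	1	B2cyc25rA	0.1	25	TRUE	A	TACGA	111680
community	2	B2cyc15B	10	15	FALSE	B	CGACA	261245
community	2	B2cyc25B	0.1	25	FALSE	B	CAGAT	340488
community	3	B2cyc15C	10	15	FALSE	C	CGACA	246313
community	3	B2cyc25C	0.1	25	FALSE	C	CAGAT	310311
community	4	unampA	NA	0	FALSE	A	NA	132639
community	5	unampB	NA	0	FALSE	B	NA	160879
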
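subject	sex	age	time_since_stroke	lesion_location	paretic_side	total	motor	balance	sensation	rom	pain	ue_total	ue_motor	le_total	le_motor
S01	F	60	20.4	Cort	R	170	75	11	3	37	44	93	45	77	30
S02	M	53	8.3	Cort	L	143	51	10	7	31	44	70	26	73	25
S04	M	61	5.3	Cort	R	207	87	10	23	43	44	130	66	77	21
S10	F	58	6.1	Cort	L	169	71	10	22	30	36	90	47	79	24
S11	F	53	17.4	Subcort	R	218	92	14	24	44	44	127	61	91	31
S13	M	46	4.4	Subcort	R>L	169	58	10	24	33	44	99	39	70	19
S14	F	52	4.3	Cort	L	152	49	8	24	37	34	68	22	84	27
S15	M	48	8.1	Cort	R	144	35	10	22	33	44	71	18	73	17
S17	F	65	6.2	Cort	L	124	32	8	4	36	44	58	14	66	18
S19	M	55	6.4	Cort	R	194	74	12	24	40	44	101	42	93	32
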
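protein_id	method	cys_a	cys_b
Q92187	known	142	292
Q92187	known	156	356
P02754	known	82	176
P02754	known	122	135
Q11130	known	68	76
Q11130	known	211	214
Q11130	known	318	321
P08037	known	134	176
P08037	known	247	266
Q09324	known	59	413
Q09324	known	100	172
Q09324	known	151	199
Q09324	known	372	381
P00698	known	24	145
P00698	known	48	133
Q92187	MassMatrix	142	292
Q92187	MassMatrix	156	356
P02754	MassMatrix	82	176
Q11130	MassMatrix	68	76
Q11130	MassMatrix	211	214
Q11130	MassMatrix	318	321
P08037	MassMatrix	134	176
P08037	MassMatrix	247	266
P00698	MassMatrix	48	133
Q92187	DCS	142	292
Q92187	DCS	156	356
P02754	DCS	82	176
P02754	DCS	122	135
Q11130	DCS	68	76
Q11130	DCS	211	214
Q11130	DCS	318	321
P08037	DCS	134	176
P08037	DCS	247	266
Q09324	DCS	372	381
P00698	DCS	24	145
P00698	DCS	48	133
Q92187	Yager	142	292
Q92187	Yager	156	356
P02754	Yager	82	176
P02754	Yager	122	135
Q11130	Yager	68	76
Q11130	Yager	211	214
Q11130	Yager	318	321
Q09324	Yager	372	381
P00698	Yager	24	145
P00698	Yager	48	133
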
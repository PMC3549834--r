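protein_id	status	cys_a	cys_b	belief
Q92187	known	142	292	NA
Q92187	known	156	356	NA
Q92187	fused	142	292	0.66
Q92187	fused	156	356	0.68
P02754	known	82	176	NA
P02754	known	122	135	NA
P02754	fused	82	176	0.49
P02754	fused	122	135	0.36
Q11130	known	68	76	NA
Q11130	known	211	214	NA
Q11130	known	318	321	NA
Q11130	fused	68	76	0.43
Q11130	fused	211	214	0.26
Q11130	fused	318	321	0.54
P08037	known	134	176	NA
P08037	known	247	266	NA
P08037	fused	134	176	0.35
P08037	fused	247	266	0.36
Q09324	known	59	413	NA
Q09324	known	100	172	NA
Q09324	known	151	199	NA
Q09324	known	372	381	NA
Q09324	fused	59	413	0.07
Q09324	fused	100	172	0.08
Q09324	fused	151	199	0.26
Q09324	fused	372	381	0.06
P00698	known	24	145	NA
P00698	known	48	133	NA
P00698	fused	24	145	0.31
P00698	fused	48	133	0.13
P00698	fused	82	98	0.10
P00698	fused	94	112	0.10
P21217	known	81	338	NA
P21217	known	91	341	NA
P21217	fused	81	338	0.67
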
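protein_id	cys_positions	bonds
REF001	5,14,31,38,51,55	1-6,2-4,3-5
REF002	12,25,40,61	1-3,2-4
REF003	8,19,33,47	1-4,2-3
REF004	22,30,58,77	1-2,3-4
REF005	10,26,44,52,70,91	1-4,2-5,3-6
REF006	6,20,27,41,63,68	1-2,3-5,4-6
REF007	15,24,39,48,55,81	1-6,2-3,4-5
REF008	11,29,36,50	1-3,2-4
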
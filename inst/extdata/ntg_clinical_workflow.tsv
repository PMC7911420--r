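subject_id	anamnestic_features	nonspecific_headache	prodrome_delay_min	premonitory_features	full_blown_delay_min	nrs_full_blown	pain_side	full_blown_features	resemblance	recovery_delay_min	nrs_recovery
EM1	0/0/1/1/1/1	1	80	0/0/0/1/0/0/0/0/0/1/0	200	7	R	0/0/1/1/1/1	1	85	1
EM2	0/0/1/0/1/1	1	31	1/0/0/1/1/0/0/0/0/0/0	140	5	R	0/0/1/0/1/1	1	50	0
EM3	1/1/1/1/0/1	1	110	0/0/0/0/1/0/0/0/1/1/0/0	155	6	L	1/0/1/1/0/1	1	70	1
EM4	1/0/1/0/1/1	0	38	1/1/0/0/0/0/0/1/0/0/0/0	70	8	B	1/0/1/0/1/1	1	95	0
EM5	0/0/1/1/1/1	0	65	0/0/0/0/1/0/0/1/1/0/0	105	6	B	1/0/1/1/1/1	0	106	1
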
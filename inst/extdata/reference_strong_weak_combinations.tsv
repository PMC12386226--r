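male	female	gca_male	gca_female	sca	PWT	heterosis_index
157	307A	22.24	13.08	53.02	157.5	0.94
157	521A	22.24	17.83	48.87	150	0.84
3618	170A	16.78	-8.91	36.62	137.5	0.69
157	I15A	22.24	1.55	6.46	137.5	0.69
3618	521A	16.78	17.83	35.76	136.5	0.68
157	170A	22.24	-8.91	35.37	136.5	0.68
E8	521A	-4.47	17.83	28.93	130	0.60
3618	428A	16.78	5.47	25.03	126	0.55
307fu	428A	3.86	5.47	24.41	125	0.54
3618	I15A	16.78	1.55	23.67	124	0.52
124fu	JinchangzaoA	-5.17	-4.79	-17.49	81.5	0.00
JinR7	428A	-21.09	5.47	-27.82	73	-0.10
14T22	4190A	-9.41	-16.78	-25.75	72	-0.12
14T22	170A	-9.41	-8.91	-29.41	70.5	-0.13
JinR7	JinchangzaoA	-21.09	-4.79	-30.24	69.5	-0.15
JinR7	4190A	-21.09	-16.78	-32.24	67	-0.18
E8	170A	-4.47	-8.91	-38.24	60.4	-0.26
JinR7	170A	-21.09	-8.91	-40.05	60	-0.26
E8	4190A	-4.47	-16.78	-43.56	54	-0.34
JinR7	QL33A	-21.09	-7.46	-45.7	49.5	-0.39
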
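parent	428A	521A	170A	I15A	307A	JinchangzaoA	4190A	QL33A
E8	4.61	3.18	5.47	3.57	3.57	6.02	3.88	4.92
307fu	3.44	3.5	4.18	4.13	1.54	5.52	3.19	3.8
14T22	4.33	2.63	5.86	3.15	3.58	5.64	4.4	5.18
157	3.64	4.71	5.39	5.74	4.65	6.09	4.98	6.14
3618	4.04	3.7	4.61	2.84	3.18	4.1	4.49	5.86
124fu	3.79	3.76	4.39	4.13	2.63	5.86	3.03	4.6
JinR7	3.87	5.07	2.46	5	2.79	5.8	3.65	6.15
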
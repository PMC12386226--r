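parent	line_type	GY	PWT	TKW	PL	PH	SD	DF	DM	TL	BIY	comprehensive_gca
428A	sterile	3.73	5.47	-0.9	-0.85	4.29	2.51	3.74	0.18	-0.13	3.9	2.4
521A	sterile	4.98	17.83	10.52	-4.05	12.81	0.6	2.78	-0.11	-0.2	7.71	7.34
170A	sterile	-4.26	-8.91	-9.83	-5.06	-13.31	2.3	4.86	-1.32	0.67	-15.51	-7.83
I15A	sterile	2	1.55	6.23	3.57	2.38	2.88	-5.53	-0.29	-0.79	5.81	3.15
307A	sterile	7.48	13.08	7.84	0.88	1.46	-2.51	-6.01	0.36	-0.18	16.4	6.11
JinchangzaoA	sterile	-1.73	-4.79	3.37	8.15	3.12	0.94	-2.98	0.36	-0.1	12.69	3.2
4190A	sterile	-8.59	-16.78	-13.97	1.6	-12.51	-1.04	2.46	0.46	0.31	-14.41	-9.25
QL33A	sterile	-3.61	-7.46	-3.25	-4.24	1.76	-5.69	0.7	0.36	0.31	-16.58	-5.13
E8	restorer	-2.15	-4.47	-7.72	3.1	-13.7	13.81	5.49	1.77	0.19	-1.72	-2.52
307fu	restorer	-1.57	3.86	14.23	1.34	12.37	-7.61	-6.49	0.83	-0.3	-7.83	2.57
14T22	restorer	-4.2	-9.41	-14	0.16	-16.55	3.16	-2.02	-0.29	0.33	-10.09	-7.76
157	restorer	11.65	22.24	9.07	3.48	5.06	-4.84	3.26	0.46	-0.37	16.61	8.61
3618	restorer	8.65	16.78	17.19	-10.99	54.92	-15.35	-5.21	-1.98	-0.79	12.72	13.44
124fu	restorer	-1.39	-5.17	-6.29	3.82	-3.11	0.04	-0.58	-1.7	-0.47	12.63	0.07
JinR7	restorer	-11.11	-21.09	-11.74	-1.01	-25.78	5.06	5.49	0.46	0.14	-18.98	-12.01
Meiza	restorer	0.12	-2.75	-0.74	0.11	-13.21	5.74	0.06	0.46	0.28	-3.35	-2.45
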
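parameter	GY	PWT	TKW	PL	PH	SD	DF	DM	TL	BIY
gca_pct	44.23	53.67	70.88	67.19	81.79	75.02	10.13	12.23	74.63	70.45
sca_pct	55.77	46.33	29.12	32.81	18.21	24.98	89.87	87.77	25.37	29.55
broad_h2	75.22	99.38	99.05	61.55	81.69	58.21	100	99.99	48.87	98.73
narrow_h2	33.27	53.33	70.21	41.35	66.81	43.67	10.13	12.23	25.33	69.55
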
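gene_id	panel	tpm_p1	tpm_p2	tpm_h
GME11100_g	p1_silent	0.01	775.83	48.93
GME7340_g	p1_silent	0.01	774.44	631.03
GME9879_g	p1_silent	0.01	747.5	1.23
GME7343_g	p1_silent	0.01	313.88	61.74
GME1292_g	p1_silent	0.01	287.98	112.42
GME3772_g	p1_silent	0.01	124.96	26.48
GME2776_g	p1_silent	0.01	39.97	7.72
GME8956_g	p1_silent	0.01	37.54	46.13
GME3790_g	p1_silent	0.01	32.5	19.82
GME11940_g	p2_silent	263.32	0.01	48.06
GME4853_g	p2_silent	256.6	0.01	8.94
GME11748_g	p2_silent	251.22	0.01	6.14
GME4080_g	p2_silent	179.97	0.01	3.16
GME2612_g	p2_silent	38.99	0.01	7.54
GME2589_g	p2_silent	38.48	0.01	2.46
GME5445_g	p2_silent	33.1	0.01	17.89
GME1642_g	p2_silent	15.29	0.01	21.92
GME3065_g	p2_silent	13.78	0.01	19.47
GME3812_g	low_both	0.01	0.01	3284.76
GME8874_g	low_both	0.01	1.39	98.04
GME2797_g	low_both	0.01	5.21	186.78
GME2976_g	low_both	0.01	9.04	71.03
GME10337_g	low_both	0.34	0.35	70.86
GME3377_g	low_both	0.5	0.01	53.49
GME7327_g	low_both	0.67	2.26	144.17
GME10002_g	low_both	0.67	5.21	67
GME10343_g	low_both	0.84	8.52	574.56
GME2777_g	low_both	1.01	1.22	66.3
GME5253_g	low_both	1.01	3.65	77.87
GME1902_g	low_both	1.01	4.34	142.94
GME3357_g	low_both	1.51	1.22	100.85
GME502_g	low_both	1.51	10.6	164.51
GME3962_g	low_both	2.18	2.43	72.08
GME5044_g	low_both	2.69	8.52	59.1
GME8904_g	low_both	2.69	15.82	85.06
GME8105_g	low_both	2.86	6.26	63.84
GME6749_g	low_both	3.19	6.95	60.51
GME4417_g	low_both	3.53	1.39	1157.53
GME5967_g	low_both	3.53	2.26	62.96
GME5307_g	low_both	3.86	1.39	80.5
GME2317_g	low_both	4.2	9.21	230.28
GME6508_g	low_both	9.58	5.04	51.74
GME6820_g	low_both	10.59	19.81	97.34
GME7379_g	low_both	11.09	2.95	2659.7
GME5714_g	low_both	11.26	4.69	126.1
GME5639_g	low_both	11.93	5.21	133.99
GME8928_g	low_both	15.12	17.9	75.42
GME910_g	low_both	18.99	13.56	136.1
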
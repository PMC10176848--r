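variable	kind	group	n	mean	sd	ci_low	ci_high	p_value
lymphocytes	immune_cell	no_met	26	1.30	0.52	1.09	1.51	0.0374
lymphocytes	immune_cell	met	29	1.61	0.55	1.40	1.82	0.0374
monocytes	immune_cell	no_met	26	0.56	0.23	0.47	0.65	0.5470
monocytes	immune_cell	met	29	0.60	0.25	0.50	0.69	0.5470
neutrophils	immune_cell	no_met	26	5.51	2.23	4.61	6.41	0.0027
neutrophils	immune_cell	met	29	7.52	2.48	6.57	8.46	0.0027
eosinophils	immune_cell	no_met	26	0.14	0.12	0.09	0.19	0.1113
eosinophils	immune_cell	met	29	0.23	0.26	0.13	0.33	0.1113
basophils	immune_cell	no_met	26	0.04	0.08	0.01	0.07	0.2893
basophils	immune_cell	met	29	0.02	0.02	0.01	0.03	0.2893
NSE	cancer_marker	no_met	22	23.10	22.12	13.29	32.91	NA
NSE	cancer_marker	met	31	30.51	32.56	18.56	42.45	NA
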
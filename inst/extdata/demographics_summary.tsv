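variable	mean_treatment	sd_treatment	n_treatment	mean_control	sd_control	n_control	t_printed	p_printed
Age	22.09	2.44	67	21.69	2.57	72	0.931	0.353
EQ	37.87	13.37	67	40.12	13.68	72	-0.984	0.326
ASQ	21.54	8.87	67	20.21	7.42	72	0.954	0.338
BDI	6.15	5.55	67	5.18	5.59	72	1.025	0.307
STAI	39.91	9.85	67	39.37	9.77	72	0.364	0.716
PANAS_POS	27.07	7.92	67	27.20	7.93	72	-0.107	0.914
PANAS_NEG	14.43	5.82	67	15.05	5.87	72	-0.653	0.514
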
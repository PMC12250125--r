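est_id	family	source_length	precursor_length	au_pct	gc_pct	n_a	n_c	n_g	n_u	mfe	amfe	mfei	source
FL647992	miR169j-5p	571	110	44.91	55.09	40	58	34	35	-55.70	-50.630	0.92	EST
JK538379	miR156f	229	127	49.28	50.72	30	41	30	39	-58.40	-45.980	0.91	EST
ES434836	miR156a-3p	789	91	41.21	58.79	27	49	51	55	-76.80	-84.400	1.44	EST
DN238517	miR482a	236	65	38.12	61.88	29	55	51	46	-88.40	-136.000	2.20	EST
FL667486	miR528-5p	674	62	45.56	54.44	52	38	67	23	-66.00	-106.000	1.95	EST
FL666615	miR397a	586	96	56.39	43.61	38	28	37	30	-58.50	-60.930	1.40	EST
FL666459	miR399a	561	136	44.12	55.88	35	50	38	47	-55.80	-41.029	0.73	EST
FL666054	miR160h	392	96	37.57	62.43	44	49	53	35	-71.30	-74.270	1.19	EST
FL659295	miR530-5p	807	65	68.33	31.67	29	29	33	29	-46.40	-71.380	2.25	EST
FL666615	miR397-5p	586	78	60.77	39.23	35	28	37	30	-56.60	-72.560	1.85	EST
FL647629	miR169a	721	116	32.22	67.78	54	39	42	45	-67.00	-57.760	0.85	EST
GABH01012340	miR166	4052	153	47.25	52.75	29	56	40	57	-59.8	-39.085	0.71	TSA
GABH01015288	miR156j	4850	81	44.79	55.21	42	34	72	44	-87.7	-108.272	2.13	TSA
GABH01000646	miR398a-3p	1536	113	50.83	49.17	50	40	49	42	-63.5	-56.195	0.96	TSA
GABH01012340	miR166e-3p	4052	141	47.51	52.49	29	55	40	57	-59.9	-42.482	0.69	TSA
GABH01012340	miR166h-3p	4052	142	48.07	51.93	30	55	39	57	-60.4	-42.535	0.78	TSA
GABH01002598	miR172i	2269	160	51.11	48.89	39	35	53	53	-51.3	-32.063	0.74	TSA
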
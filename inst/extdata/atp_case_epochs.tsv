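chain	epoch	TN	FN	FP	TP	F1	MCC
1OJL_E	20	262	1	27	14	50	0.533
1OJL_E	40	281	0	8	15	78.95	0.796
1OJL_E	60	285	1	4	14	84.85	0.844
1OJL_E	83	288	1	1	14	93.33	0.93
2Z08_A	20	83	1	35	18	50	0.462
2Z08_A	40	105	2	13	17	69.39	0.656
2Z08_A	60	112	2	6	17	80.95	0.78
2Z08_A	83	113	1	5	18	85.71	0.837
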
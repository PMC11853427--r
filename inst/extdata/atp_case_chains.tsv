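chain	true_label_0	predicted_label_0	true_label_1	predicted_label_1	F1	MCC
2BEK_A	238	238	19	19	100	1
1OJL_E	289	289	15	15	93.33	0.93
1Y56_A	472	465	21	28	85.71	0.86
1N5I_A	210	207	4	7	72.73	0.751
3HAV_A	286	287	13	12	96	0.959
1Y8Q_B	621	620	19	20	92.31	0.921
1A49_A	516	514	14	16	93.33	0.934
2HS0_A	570	563	33	40	82.19	0.815
1ESQ_A	269	267	15	17	87.5	0.869
1YID_B	340	333	11	18	68.97	0.7
1NSF_A	253	253	20	20	80	0.784
1QHG_A	714	705	10	19	68.97	0.721
1H4Q_B	462	461	15	16	77.42	0.767
1KVK_A	379	375	16	20	83.33	0.831
1JJV_A	194	194	12	12	91.67	0.912
1MJH_A	142	141	20	21	92.68	0.917
3K5H_A	383	383	20	20	95	0.947
2Z08_A	118	114	19	23	85.71	0.837
3MEY_A	328	329	18	17	97.14	0.97
3C5E_A	551	547	19	23	90.48	0.906
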
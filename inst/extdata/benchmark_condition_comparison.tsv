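subject	approach	roi	R_q	R_o
1	standard	whole	0.00	0.00
2	standard	whole	0.13	0.00
3	standard	whole	0.66	0.31
4	standard	whole	0.71	0.04
5	standard	whole	0.94	0.71
1	guided	whole	0.54	0.08
2	guided	whole	0.71	0.51
3	guided	whole	0.34	0.32
4	guided	whole	0.75	0.36
5	guided	whole	0.90	0.49
1	standard	left	0.00	0.00
2	standard	left	0.13	0.00
3	standard	left	0.11	0.11
4	standard	left	0.29	0.00
5	standard	left	0.94	0.77
1	guided	left	0.69	0.07
2	guided	left	0.63	0.56
3	guided	left	0.39	0.37
4	guided	left	0.82	0.43
5	guided	left	0.83	0.65
1	standard	navigated	0.00	0.00
2	standard	navigated	0.17	0.00
3	standard	navigated	0.17	0.17
4	standard	navigated	0.00	0.00
5	standard	navigated	0.89	0.89
1	guided	navigated	0.13	0.00
2	guided	navigated	0.70	0.70
3	guided	navigated	0.44	0.44
4	guided	navigated	0.85	0.59
5	guided	navigated	0.87	0.73
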
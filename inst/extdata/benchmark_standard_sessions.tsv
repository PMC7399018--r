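subject	condition	delta_map_pct	delta_hr_pct	R_q	R_o
1	same_day	3.1	11.8	0.00	0.00
2	same_day	14.2	12.5	0.41	0.17
3	same_day	5.5	20.7	0.73	0.45
4	same_day	13.2	6.8	0.89	0.36
5	same_day	4.7	9.5	0.90	0.68
1	across_days	8.3	8.9	0.00	0.00
2	across_days	5.1	6.8	0.13	0.00
3	across_days	8.3	14.5	0.66	0.31
4	across_days	8.3	4.0	0.71	0.04
5	across_days	5.1	9.0	0.94	0.71
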
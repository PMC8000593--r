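shuffle	lesion_sensitivity	lesion_precision	patient_sensitivity	patient_specificity
1	0.69	0.83	1.00	0.83
2	0.70	0.86	0.75	0.91
3	0.68	0.87	0.88	0.73
4	0.68	0.97	0.88	1.00
5	0.71	0.94	1.00	1.00
6	0.70	0.92	1.00	1.00
7	0.77	0.87	1.00	0.79
8	0.71	0.92	1.00	1.00
9	0.73	0.91	1.00	0.91
10	0.78	0.94	0.88	1.00
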
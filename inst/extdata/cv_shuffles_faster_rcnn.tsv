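shuffle	lesion_sensitivity	lesion_precision	patient_sensitivity	patient_specificity
1	0.77	0.66	1.00	0.90
2	0.67	0.59	1.00	0.70
3	0.75	0.68	1.00	0.60
4	0.65	0.50	0.86	0.36
5	0.68	0.59	0.88	0.64
6	0.74	0.67	0.88	1.00
7	0.56	0.78	1.00	0.73
8	0.70	0.54	0.88	0.82
9	0.72	0.74	0.89	0.70
10	0.48	0.77	0.75	0.82
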
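genome_id	correction_method	completeness	contamination
PAO1-tig00000001	uncorrected	84.28	0.66
PAO1-tig00000003	uncorrected	64.34	1.56
PAO1-tig00000117	uncorrected	82.46	0.15
PAO1-tig00026549	uncorrected	86.57	0.50
PAO1-tig00026557	uncorrected	75.56	2.70
PAO1-tig00026560	uncorrected	71.51	1.59
PAO1-tig00198536	uncorrected	74.83	2.74
PAO2-tig00000001	uncorrected	70.90	0.03
PAO2-tig00000013	uncorrected	45.13	0.00
PAO3A-tig00000003	uncorrected	75.75	0.10
PAO3A-tig00000011	uncorrected	82.70	2.23
PAO3A-tig00000024	uncorrected	79.79	0.81
PAO3A-tig00000209	uncorrected	87.00	0.00
PAO3A-tig00018026	uncorrected	41.99	0.28
PAO3A-tig00139797	uncorrected	91.56	0.48
PAO3B-tig00000024	uncorrected	89.02	0.23
PAO3B-tig00000027	uncorrected	73.78	0.42
PAO4-tig00000001	uncorrected	93.04	1.90
PAO4-tig00000030	uncorrected	76.77	1.30
PAO4-tig00000046	uncorrected	91.85	0.47
PAO4-tig00000079	uncorrected	80.26	0.00
PAO4-tig00000228	uncorrected	70.80	0.02
PAO1-tig00000001	megan_lr	95.28	1.11
PAO1-tig00000003	megan_lr	92.82	0.25
PAO1-tig00000117	megan_lr	97.53	0.15
PAO1-tig00026549	megan_lr	94.64	0.50
PAO1-tig00026557	megan_lr	94.19	1.58
PAO1-tig00026560	megan_lr	93.99	0.55
PAO1-tig00198536	megan_lr	92.57	1.98
PAO2-tig00000001	megan_lr	93.85	0.00
PAO2-tig00000013	megan_lr	94.49	0.18
PAO3A-tig00000003	megan_lr	94.56	0.28
PAO3A-tig00000011	megan_lr	94.31	2.17
PAO3A-tig00000024	megan_lr	96.92	0.00
PAO3A-tig00000209	megan_lr	95.38	0.00
PAO3A-tig00018026	megan_lr	93.47	1.09
PAO3A-tig00139797	megan_lr	99.04	0.48
PAO3B-tig00000024	megan_lr	98.10	0.23
PAO3B-tig00000027	megan_lr	93.16	0.42
PAO4-tig00000001	megan_lr	98.64	2.07
PAO4-tig00000030	megan_lr	97.10	2.30
PAO4-tig00000046	megan_lr	96.30	0.47
PAO4-tig00000079	megan_lr	94.79	0.00
PAO4-tig00000228	megan_lr	94.81	0.00
PAO1-tig00000001	medaka	93.91	1.59
PAO1-tig00000003	medaka	84.84	0.90
PAO1-tig00000117	medaka	94.82	0.15
PAO1-tig00026549	medaka	97.13	0.50
PAO1-tig00026557	medaka	95.24	1.58
PAO1-tig00026560	medaka	94.24	0.00
PAO1-tig00198536	medaka	94.64	2.48
PAO2-tig00000001	medaka	89.33	0.03
PAO2-tig00000013	medaka	89.16	0.59
PAO3A-tig00000003	medaka	93.78	0.50
PAO3A-tig00000011	medaka	93.70	2.26
PAO3A-tig00000024	medaka	89.46	0.32
PAO3A-tig00000209	medaka	96.80	0.00
PAO3A-tig00018026	medaka	81.67	1.09
PAO3A-tig00139797	medaka	97.05	0.55
PAO3B-tig00000024	medaka	93.63	0.23
PAO3B-tig00000027	medaka	85.11	0.63
PAO4-tig00000001	medaka	97.97	2.07
PAO4-tig00000030	medaka	91.63	1.52
PAO4-tig00000046	medaka	97.64	0.47
PAO4-tig00000079	medaka	89.66	0.66
PAO4-tig00000228	medaka	77.98	0.08
PAO1-tig00000001	racon	87.88	1.62
PAO1-tig00000003	racon	78.21	0.74
PAO1-tig00000117	racon	90.99	0.15
PAO1-tig00026549	racon	91.45	0.50
PAO1-tig00026557	racon	86.16	1.58
PAO1-tig00026560	racon	86.70	0.30
PAO1-tig00198536	racon	88.68	2.23
PAO2-tig00000001	racon	83.64	1.19
PAO2-tig00000013	racon	86.32	0.38
PAO3A-tig00000003	racon	83.48	0.10
PAO3A-tig00000011	racon	89.08	1.44
PAO3A-tig00000024	racon	84.66	0.32
PAO3A-tig00000209	racon	94.60	0.00
PAO3A-tig00018026	racon	66.02	1.27
PAO3A-tig00139797	racon	97.02	0.48
PAO3B-tig00000024	racon	90.53	0.00
PAO3B-tig00000027	racon	81.80	0.16
PAO4-tig00000001	racon	96.58	2.06
PAO4-tig00000030	racon	85.14	1.63
PAO4-tig00000046	racon	94.90	0.50
PAO4-tig00000079	racon	89.85	0.72
PAO4-tig00000228	racon	77.13	0.00
PAO1-tig00000001	multiple	94.71	1.11
PAO1-tig00000003	multiple	87.74	0.74
PAO1-tig00000117	multiple	94.82	0.15
PAO1-tig00026549	multiple	96.73	0.50
PAO1-tig00026557	multiple	95.58	1.58
PAO1-tig00026560	multiple	94.52	0.00
PAO1-tig00198536	multiple	94.39	2.48
PAO2-tig00000001	multiple	90.88	0.03
PAO2-tig00000013	multiple	91.52	0.12
PAO3A-tig00000003	multiple	93.52	0.50
PAO3A-tig00000011	multiple	95.05	1.91
PAO3A-tig00000024	multiple	89.86	0.32
PAO3A-tig00000209	multiple	97.32	0.00
PAO3A-tig00018026	multiple	77.17	1.37
PAO3A-tig00139797	multiple	97.05	0.48
PAO3B-tig00000024	multiple	91.71	0.39
PAO3B-tig00000027	multiple	87.97	0.73
PAO4-tig00000001	multiple	97.95	2.06
PAO4-tig00000030	multiple	91.87	1.11
PAO4-tig00000046	multiple	97.40	0.47
PAO4-tig00000079	multiple	90.87	0.66
PAO4-tig00000228	multiple	78.18	0.00
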
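genome_id	length_bp	n_cds	n_rrna_operons	n_trna	completeness	contamination	circular
PAO1-tig00000001	5190177	5116	2	53	95.28	1.11	FALSE
PAO1-tig00000003	4268816	5123	1	36	92.82	0.25	FALSE
PAO1-tig00000117	2656706	3153	1	38	97.53	0.15	FALSE
PAO1-tig00026549	4352448	4225	1	46	94.64	0.50	FALSE
PAO1-tig00026557	3138394	3619	2	44	94.19	1.58	FALSE
PAO1-tig00026560	4262704	4373	2	37	93.99	0.55	FALSE
PAO1-tig00198536	3913768	3521	2	38	92.57	1.98	FALSE
PAO2-tig00000001	5027886	4558	2	46	93.85	0.00	TRUE
PAO2-tig00000013	3452123	3382	2	46	94.49	0.18	FALSE
PAO3A-tig00000003	3666458	3454	1	53	94.56	0.28	FALSE
PAO3A-tig00000011	3813965	3532	2	53	94.31	2.17	TRUE
PAO3A-tig00000024	2740818	2753	1	44	96.92	0.00	TRUE
PAO3A-tig00000209	3302829	3190	1	47	95.38	0.00	FALSE
PAO3A-tig00018026	4685957	4742	1	48	93.47	1.09	FALSE
PAO3A-tig00139797	3548924	3508	2	47	99.04	0.48	TRUE
PAO3B-tig00000024	3282734	2937	2	51	98.10	0.23	TRUE
PAO3B-tig00000027	3375962	3179	1	53	93.16	0.42	TRUE
PAO4-tig00000001	3950501	3652	2	58	98.64	2.07	TRUE
PAO4-tig00000030	4541730	4623	2	47	97.10	2.30	TRUE
PAO4-tig00000046	3961963	3725	2	51	96.30	0.47	TRUE
PAO4-tig00000079	2921657	3197	9	59	94.79	0.00	TRUE
PAO4-tig00000228	4261978	4404	2	50	94.81	0.00	FALSE
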
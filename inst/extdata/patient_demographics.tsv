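code	cohort	n_visits	span_months	sex	age_at_onset	age_at_first_visit	alsfrsr_slope	onset_site
S1	discovery	4	28	F	43	46	0.32	Limb
S2	discovery	4	24	M	53	57	0.29	Limb
S3	discovery	4	20	F	31	65	0.21	Bulbar
S4	discovery	4	18	M	56	57	0.00	Limb
S5	discovery	3	6	F	34	36	0.28	Limb
F1	discovery	4	13	M	56	57	1.69	Bulbar
F2	discovery	4	12	F	65	67	1.66	Limb
F3	discovery	3	8	M	54	55	1.50	Limb
F4	discovery	5	35	F	59	59	1.00	Limb
F5	discovery	4	21	M	52	53	2.33	Limb
F6	discovery	4	20	M	40	41	2.67	Limb
S6	validation	3	12	F	58	65	0.03	Limb
S7	validation	3	8	M	38	41	0.07	Limb
S8	validation	3	11	F	64	66	0.48	Bulbar
S9	validation	3	8	F	27	43	0.03	Limb
S10	validation	3	9	M	46	54	0.17	Limb
S11	validation	3	9	M	63	66	0.12	Limb
F7	validation	3	8	M	NA	51	1.50	Limb
F8	validation	3	7	F	52	53	1.37	Limb
F9	validation	3	6	M	54	55	2.67	Limb
F10	validation	3	8	F	58	59	2.34	Limb
F11	validation	3	8	M	75	77	1.05	Limb
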
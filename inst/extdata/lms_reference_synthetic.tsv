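sex	gestational_weeks	L	M	S
F	22	1	458.4	0.11
M	22	1	496.6	0.11
F	23	1	544.9	0.11
M	23	1	590.3	0.11
F	24	1	643	0.11
M	24	1	696.6	0.11
F	25	1	753.5	0.11
M	25	1	816.3	0.11
F	26	1	876.7	0.11
M	26	1	949.7	0.11
F	27	1	1012.8	0.11
M	27	1	1097.2	0.11
F	28	1	1161.9	0.11
M	28	1	1258.7	0.11
F	29	1	1323.5	0.11
M	29	1	1433.8	0.11
F	30	1	1496.9	0.11
M	30	1	1621.7	0.11
F	31	1	1681.2	0.11
M	31	1	1821.3	0.11
F	32	1	1874.7	0.11
M	32	1	2031	0.11
F	33	1	2075.8	0.11
M	33	1	2248.8	0.11
F	34	1	2282.3	0.11
M	34	1	2472.5	0.11
F	35	1	2491.6	0.11
M	35	1	2699.2	0.11
F	36	1	2700.9	0.11
M	36	1	2926	0.11
F	37	1	2907.1	0.11
M	37	1	3149.4	0.11
F	38	1	3107	0.11
M	38	1	3365.9	0.11
F	39	1	3297.2	0.11
M	39	1	3572	0.11
F	40	1	3474.4	0.11
M	40	1	3763.9	0.11
F	41	1	3635.3	0.11
M	41	1	3938.2	0.11
F	42	1	3776.7	0.11
M	42	1	4091.5	0.11
F	43	1	3896	0.11
M	43	1	4220.7	0.11
F	44	1	3990.8	0.11
M	44	1	4323.3	0.11
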
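measure	mean_A	sd_A	mean_B	sd_B	n_A	n_B	t_reported	exact
Age	22.64	5.46	22.66	5.47	14	14	-0.01	TRUE
OSpan	32.00	9.57	33.21	12.15	14	14	-0.29	TRUE
RotSpan	12.29	6.37	14.14	5.96	14	14	-0.80	FALSE
SymSpan	16.07	7.78	12.93	6.22	14	14	1.18	TRUE
IPI_MindWandering	3.36	0.85	3.32	0.95	14	14	0.12	TRUE
PRMQ_Retrospective	3.46	0.69	3.71	0.65	14	14	-0.98	FALSE
PRMQ_Prospective	3.02	0.61	3.36	0.77	14	14	-1.32	FALSE
TMS_Decentering	13.36	3.50	11.93	3.36	14	14	1.10	TRUE
TMS_Curiosity	18.50	4.26	15.36	4.41	14	14	1.92	TRUE
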
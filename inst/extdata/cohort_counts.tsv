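abbrev	icd10	group	faroe_n	faroe_m	faroe_f	faroe_pct	nd_n	nd_m	nd_f	nd_pct	registry_pct
HL	C81	LPD	19	12	7	8.7	11	8	3	4.0	6
FL	C82	LPD	14	9	5	6.4	19	13	6	6.9	12
MCL	C82.7	LPD	0	0	0	NA	4	4	0	1.4	<1
DLBCL	C83.3	LPD	34	21	13	15.6	16	9	7	5.8	25
TNHL	C84	LPD	6	2	4	2.7	2	2	0	0.7	2
MONOC	C85.7	LPD	0	0	0	NA	4	1	3	1.4	2
NHL NOS	C85.9	LPD	25	14	11	11.4	9	4	5	3.3	6
WA	C88	LPD	2	1	1	0.9	8	5	3	2.9	3
MM	C90	LPD	50	31	19	22.8	10	6	4	3.6	14
ALL	C91.0	LPD	16	10	6	7.3	4	2	2	1.4	4
CLL	C91.1	LPD	50	29	21	22.8	181	98	83	65.6	22
PLL	C91.3	LPD	2	1	1	0.9	2	0	2	0.7	1
HCL	C91.4	LPD	1	1	0	0.5	1	0	1	0.4	1
LGTCL	C91.7	LPD	0	0	0	NA	3	2	1	1.1	<1
MGUS	D47.2	LPD	0	0	0	NA	2	1	1	0.7	2
AML	C92.0	MPD	44	28	16	50.6	9	6	3	37.6	70
CML	C92.1	MPD	14	9	5	16.1	3	1	2	12.5	15
PV	D45	MPD	4	2	2	4.6	6	4	2	25.0	5
MDS	D46	MPD	2	0	2	2.3	2	1	1	8.3	5
MF	D47.1	MPD	8	4	4	9.2	1	0	1	4.2	5
ET	D47.3	MPD	0	0	0	NA	3	1	2	12.5	<1
ML NOS	C92.9	MPD	15	9	6	17.2	0	0	0	NA	<1
L NOS	C95.9	OTHER	7	2	5	NA	1	1	0	NA	NA
MH	C96.1	OTHER	2	0	2	NA	0	0	0	NA	NA
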
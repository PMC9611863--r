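gene	database	target_tpm	max_other	median_other
ZNF473	HPA	76.4	11.1	4.25
ZNF473	ENCODE	79	8	2.5
ZNF473	GTEx	49.1	8.3	3.25
ZNF473	Illumina	46	8	4
ZBTB32	HPA	43.3	7.5	0.15
ZBTB32	ENCODE	84	4	0
ZBTB32	GTEx	109.3	6.5	0.3
ZBTB32	Illumina	32	5	0.4
ZNF541	HPA	19.2	1.7	0.1
ZNF541	ENCODE	40	1	0.3
ZNF541	GTEx	45.7	2.7	0.3
ZNF541	Illumina	18	2	0.3
ZSCAN5A	HPA	34.6	11.3	3.4
ZSCAN5A	ENCODE	12	2	0.95
ZSCAN5A	GTEx	14.4	2.3	1.2
ZSCAN5A	Illumina	12	3	1
ZNF487	HPA	51.4	9.9	2.95
ZNF487	ENCODE	28	7	2
ZNF487	GTEx	23.2	4.4	2.1
ZNF487	Illumina	21	5	2
PRDM9	HPA	7	1.7	0
PRDM9	ENCODE	9	0	0
PRDM9	GTEx	6.9	0	0
PRDM9	Illumina	6	0	0
ZNF560	HPA	11.9	1.2	0
ZNF560	ENCODE	15	0.2	0
ZNF560	GTEx	15.5	0.6	0
ZNF560	Illumina	12	0.3	0
CTCFL	HPA	20.4	0.8	0.3
CTCFL	ENCODE	14	0.2	0
CTCFL	GTEx	7.5	0.1	0
CTCFL	Illumina	17	0.5	0.2
ZNF165	HPA	35.8	7.4	1.55
ZNF165	ENCODE	46	15	2
ZNF165	GTEx	45.6	7.6	1.35
ZNF165	Illumina	49	9	2
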
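gene	normal_median_tpm	tumor_median_tpm
ZBTB32	93.0	0.93
PRDM9	4.52	0.05
ZNF541	27.4	0.36
KLF17	15.8	0.31
CTCFL	9.11	0.20
ZNF479	3.34	0.13
ZFHX2	17.7	1.09
ZNF487	33.0	2.48
ZNF433	32.9	2.61
ZSCAN5B	2.25	0.18
ZNF165	21.3	2.20
ZNF563	15.3	1.98
ZNF473	39.1	6.37
ZSCAN5A	34.6	5.94
ZNF628	31.7	5.45
ZNF233	9.55	1.68
ZNF829	12.6	3.28
ZNF646	32.7	8.83
ZNF689	22.4	6.40
ZNF318	46.8	14.3
BNC1	19.6	6.45
ZNF574	37.0	15.7
ZNF728	5.86	3.44
ZNF560	8.89	7.53
ZFP42	2.54	43.0
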
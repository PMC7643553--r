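chrom	LincRNA	NAT-lncRNA	Intronic-lncRNA	Sense-lncRNA
Chr1	61	59	4	5
Chr2	44	47	2	3
Chr3	46	46	1	2
Chr4	38	41	1	4
Chr5	26	45	1	3
Chr6	24	31	1	2
Chr7	21	23	0	4
Chr8	22	30	1	1
Chr9	13	33	0	2
Chr10	11	19	0	1
Chr11	19	15	0	1
Chr12	13	28	1	2
Chr13	19	13	0	0
Chr14	24	13	0	1
Chr15	11	16	2	1
Chr16	12	20	1	0
others	299	102	17	15
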
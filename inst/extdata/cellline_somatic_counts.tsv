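sample	category	count	novel_count
HCC1143	frameshift_deletion	1	1
HCC1143	frameshift_insertion	0	0
HCC1143	nonframeshift_deletion	0	0
HCC1143	nonsynonymous_SNV	37	2
HCC1143	stopgain_SNV	3	0
HCC1143	stoploss_SNV	0	0
HCC1143	synonymous_SNV	5	3
HCC1143	unknown	0	0
HCC1143	splicing	0	0
HCC1143	UTR3	5	5
HCC1143	UTR5	1	1
HCC1143	intronic	9	9
HCC1187	frameshift_deletion	1	0
HCC1187	frameshift_insertion	4	2
HCC1187	nonframeshift_deletion	2	0
HCC1187	nonsynonymous_SNV	46	3
HCC1187	stopgain_SNV	5	0
HCC1187	stoploss_SNV	0	0
HCC1187	synonymous_SNV	4	3
HCC1187	unknown	0	0
HCC1187	splicing	0	0
HCC1187	UTR3	4	4
HCC1187	UTR5	0	0
HCC1187	intronic	6	6
HCC1395	frameshift_deletion	1	1
HCC1395	frameshift_insertion	0	0
HCC1395	nonframeshift_deletion	0	0
HCC1395	nonsynonymous_SNV	133	26
HCC1395	stopgain_SNV	6	0
HCC1395	stoploss_SNV	0	0
HCC1395	synonymous_SNV	29	21
HCC1395	unknown	1	1
HCC1395	splicing	6	0
HCC1395	UTR3	26	26
HCC1395	UTR5	8	8
HCC1395	intronic	76	72
HCC1937	frameshift_deletion	0	0
HCC1937	frameshift_insertion	0	0
HCC1937	nonframeshift_deletion	0	0
HCC1937	nonsynonymous_SNV	46	16
HCC1937	stopgain_SNV	5	1
HCC1937	stoploss_SNV	0	0
HCC1937	synonymous_SNV	18	14
HCC1937	unknown	0	0
HCC1937	splicing	2	1
HCC1937	UTR3	18	18
HCC1937	UTR5	4	4
HCC1937	intronic	25	23
HCC1954	frameshift_deletion	1	0
HCC1954	frameshift_insertion	1	0
HCC1954	nonframeshift_deletion	0	0
HCC1954	nonsynonymous_SNV	33	0
HCC1954	stopgain_SNV	1	0
HCC1954	stoploss_SNV	0	0
HCC1954	synonymous_SNV	5	3
HCC1954	unknown	0	0
HCC1954	splicing	1	0
HCC1954	UTR3	3	3
HCC1954	UTR5	2	2
HCC1954	intronic	11	11
HCC38	frameshift_deletion	2	1
HCC38	frameshift_insertion	0	0
HCC38	nonframeshift_deletion	0	0
HCC38	nonsynonymous_SNV	38	9
HCC38	stopgain_SNV	1	0
HCC38	stoploss_SNV	1	0
HCC38	synonymous_SNV	7	3
HCC38	unknown	0	0
HCC38	splicing	1	0
HCC38	UTR3	3	3
HCC38	UTR5	2	2
HCC38	intronic	8	7
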
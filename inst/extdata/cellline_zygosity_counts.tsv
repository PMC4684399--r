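sample	heterozygous_high	homozygous_high
HCC1143	51	10
HCC1187	49	23
HCC1395	198	88
HCC1937	87	31
HCC1954	54	4
HCC38	51	12
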
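sample	tier	validated	analyzed
HCC1143	high_confidence	7	8
HCC1187	high_confidence	7	7
HCC1395	high_confidence	49	54
HCC1937	high_confidence	40	40
HCC1954	high_confidence	1	2
HCC38	high_confidence	7	7
HCC1143	low_confidence	3	13
HCC1187	low_confidence	0	6
HCC1395	low_confidence	6	14
HCC1937	low_confidence	2	7
HCC1954	low_confidence	1	4
HCC38	low_confidence	2	10
HCC1143	catalogue_missed	2	3
HCC1187	catalogue_missed	4	5
HCC1395	catalogue_missed	4	10
HCC1937	catalogue_missed	6	8
HCC1954	catalogue_missed	3	5
HCC38	catalogue_missed	4	5
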
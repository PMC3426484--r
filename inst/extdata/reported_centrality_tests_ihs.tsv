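centrality	rank_sum_1	rank_sum_2	U	Z	p	n1	n2
Betweenness	1151.00	502.00	331.00	-0.16	0.8749	40	17
Centroid	1201.50	451.50	298.50	0.73	0.4674	40	17
Closeness	1173.50	479.50	326.50	0.24	0.8135	40	17
Eccentricity	1157.00	496.00	337.00	-0.05	0.9578	40	17
Node Degree	1183.50	469.50	316.50	0.42	0.6758	40	17
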
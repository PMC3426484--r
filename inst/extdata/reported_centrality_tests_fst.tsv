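centrality	rank_sum_1	rank_sum_2	U	Z	p	n1	n2
Betweenness	1425.50	227.50	172.50	1.32	0.1885	47	10
Centroid	1357.50	295.50	229.50	-0.12	0.9078	47	10
Closeness	1404.50	248.50	193.50	0.87	0.3830	47	10
Eccentricity	1485.00	168.00	113.00	2.59	0.0097	47	10
Node Degree	1254.00	399.00	126.00	-2.33	0.0196	47	10
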
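symbol	gene_id	style	outdegree	indegree	degree
PLCB1	23236	down	3	5	8
NRAS	4893	up	6	2	8
PIK3CD	5293	down	4	3	7
PIK3CA	5290	down	4	3	7
PIK3R1	5295	down	4	3	7
HDAC4	9759	up	0	6	6
HDAC8	55869	up	0	6	6
CRKL	1399	down	1	4	5
RAB7A	7879	down	1	4	5
ITGB3	3690	down	1	3	4
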
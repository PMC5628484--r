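name	style	outdegree	indegree	degree
MAPK signaling pathway	up_down	27	3	30
Apoptosis	down	20	2	22
Pathways in cancer	up_down	0	21	21
p53 signaling pathway	up	14	1	15
ErbB signaling pathway	down	5	6	11
Cytokine-cytokine receptor interaction	down	11	0	11
Focal adhesion	down	5	5	10
Jak-STAT signaling pathway	down	5	4	9
Pancreatic cancer	up_down	2	6	8
mTOR signaling pathway	down	4	3	7
Glioma	up_down	2	5	7
VEGF signaling pathway	down	4	3	7
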
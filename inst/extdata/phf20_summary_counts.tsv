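quantity	up	down
deg_genes	175	365
go_terms	111	125
kegg_pathways	41	106
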
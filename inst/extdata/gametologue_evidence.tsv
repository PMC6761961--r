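gene	type	ds	y_in_outgroup
NIBANY/FAM129BY	protein_coding	0.42	yes
CAMSAP1Y	protein_coding	0.36	yes
UnknownY	protein_coding	0.27	yes
EHMT1Y	protein_coding	0.26	yes
CACNA1BY	protein_coding	0.24	yes
AKIY	protein_coding	0.22	no
MEGF9Y	protein_coding	0.17	no
RAB14Y	protein_coding	0.11	no
HSPA5Y	protein_coding	0.088	no
GOLGA2Y	protein_coding	0.083	no
ZBTB34Y	protein_coding	0.069	no
CCDC183Y	protein_coding	NA	no
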
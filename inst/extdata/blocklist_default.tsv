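# Default blocklist: abundant serum protein families prone to non-specific
# binding to protein-G beads in immunoprecipitation experiments.
# One rule per line: match_type<TAB>pattern
# match types: name_substring (case-insensitive), gene_prefix, accession_exact
#
# hemoglobins
name_substring	hemoglobin
gene_prefix	HB
# haptoglobin
name_substring	haptoglobin
# hemopexin
name_substring	hemopexin
# immunoglobulins
name_substring	immunoglobulin
gene_prefix	IGH
gene_prefix	IGK
gene_prefix	IGL
# keratins
name_substring	keratin
gene_prefix	KRT
# apolipoproteins
name_substring	apolipoprotein
gene_prefix	APO
# serum albumin
name_substring	albumin
gene_prefix	ALB
# complement
name_substring	complement
gene_prefix	C1Q
gene_prefix	C1R
gene_prefix	C1S
gene_prefix	C2
gene_prefix	C3
gene_prefix	C4
gene_prefix	C5
gene_prefix	C6
gene_prefix	C7
gene_prefix	C8
gene_prefix	C9
gene_prefix	CF
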
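quantity	value
genome_length_bp	621884
protein_exon_bp	31721
protein_intron_bp	29861
trna_bp	2234
rrna_bp	8826
n_protein_genes	35
n_rrna_genes	4
n_trna_genes	29
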
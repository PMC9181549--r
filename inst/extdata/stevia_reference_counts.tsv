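quantity	value
svgly_genes_total	103
svgly_genes_with_primer	35
control_genes_total	103
control_genes_with_primer	16
gypsy_genome_percent	36.7
copia_genome_percent	18.7
undetermined_genome_percent	0.4
total_ltr_genome_percent	55.8
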
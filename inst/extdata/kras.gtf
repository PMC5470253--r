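##gff-version 2
##source-version rtracklayer 1.62.0
##date 2026-09-26
chrK	skipquant	exon	1	200	.	+	.	gene_id "Kras"; transcript_id "Kras"; exon_number "1"
chrK	skipquant	exon	501	622	.	+	.	gene_id "Kras"; transcript_id "Kras"; exon_number "2"
chrK	skipquant	exon	1001	1400	.	+	.	gene_id "Kras"; transcript_id "Kras"; exon_number "3"
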
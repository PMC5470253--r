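##gff-version 2
##source-version rtracklayer 1.62.0
##date 2026-09-26
chrD	skipquant	exon	1	300	.	+	.	gene_id "Dmd"; transcript_id "Dmd"; exon_number "22"
chrD	skipquant	exon	1001	1213	.	+	.	gene_id "Dmd"; transcript_id "Dmd"; exon_number "23"
chrD	skipquant	exon	2001	2300	.	+	.	gene_id "Dmd"; transcript_id "Dmd"; exon_number "24"
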
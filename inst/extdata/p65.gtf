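##gff-version 2
##source-version rtracklayer 1.62.0
##date 2026-09-26
chrP	skipquant	exon	1	150	.	+	.	gene_id "p65"; transcript_id "p65"; exon_number "4"
chrP	skipquant	exon	1001	1100	.	+	.	gene_id "p65"; transcript_id "p65"; exon_number "5"
chrP	skipquant	exon	1501	1600	.	+	.	gene_id "p65"; transcript_id "p65"; exon_number "6"
chrP	skipquant	exon	2101	2200	.	+	.	gene_id "p65"; transcript_id "p65"; exon_number "7"
chrP	skipquant	exon	3001	3150	.	+	.	gene_id "p65"; transcript_id "p65"; exon_number "8"
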
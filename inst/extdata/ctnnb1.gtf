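##gff-version 2
##source-version rtracklayer 1.62.0
##date 2026-09-26
chrC	skipquant	exon	1	150	.	+	.	gene_id "Ctnnb1"; transcript_id "Ctnnb1"; exon_number "2"
chrC	skipquant	exon	401	628	.	+	.	gene_id "Ctnnb1"; transcript_id "Ctnnb1"; exon_number "3"
chrC	skipquant	exon	901	1084	.	+	.	gene_id "Ctnnb1"; transcript_id "Ctnnb1"; exon_number "4"
chrC	skipquant	exon	1301	1399	.	+	.	gene_id "Ctnnb1"; transcript_id "Ctnnb1"; exon_number "5"
chrC	skipquant	exon	1601	1750	.	+	.	gene_id "Ctnnb1"; transcript_id "Ctnnb1"; exon_number "6"
chrC	skipquant	exon	2001	2200	.	+	.	gene_id "Ctnnb1"; transcript_id "Ctnnb1"; exon_number "7"
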
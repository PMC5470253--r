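#' Write alignment records as SAM
#'
#' Serialises a data.frame of alignment records (as produced by the read
#' simulators) to a SAM file with proper `@HD`/`@SQ` headers, so the file
#' is consumable by samtools and by [read_alignments()].
#'
#' @param aln `data.frame` with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual` (the latter two may be `"*"`).
#' @param path Output `.sam` path.
#' @param seqlengths Named integer vector of reference lengths for the
#'   `@SQ` lines.
#' @param comments Optional character vector written as `@CO` lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, seqlengths, comments = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)),
           if (!is.null(comments)) paste0("@CO\t", comments))
  body <- if (nrow(aln) > 0L) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
            aln$qname, as.integer(aln$flag), aln$rname, as.integer(aln$pos),
            as.integer(aln$mapq), aln$cigar, aln$seq, aln$qual)
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read spliced/gapped alignments from SAM or BAM
#'
#' Thin wrapper over Rsamtools/GenomicAlignments: SAM input is converted
#' to a temporary BAM and read back as a `GAlignments` object carrying the
#' read sequence.
#'
#' @param path `.sam` or `.bam` file.
#' @return A `GAlignments` object with metadata columns `qname` and `seq`.
#' @export
read_alignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  bam <- if (ext == "sam") {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  param <- Rsamtools::ScanBamParam(what = c("qname", "seq"))
  GenomicAlignments::readGAlignments(bam, param = param, use.names = FALSE)
}

#' Write reads as FASTQ
#'
#' @param reads Named character vector or `DNAStringSet` of read sequences.
#' @param path Output `.fastq` path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dss <- Biostrings::DNAStringSet(reads)
  if (is.null(names(dss))) names(dss) <- paste0("read", seq_along(dss))
  Biostrings::writeXStringSet(dss, path, format = "fastq")
  invisible(path)
}

#' Read a FASTQ file as a DNAStringSet
#' @param path `.fastq` path.
#' @return `DNAStringSet`.
#' @export
read_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

# Internal: write a TSV with '#'-prefixed provenance header lines.
write_tsv_prov <- function(df, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance))
    writeLines(paste0("# ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Internal: read a TSV written by write_tsv_prov.
read_tsv_prov <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
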
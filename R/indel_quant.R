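#' Left-align an indel against a reference sequence
#'
#' Shifts an insertion or deletion to its lowest compatible reference
#' coordinate, the standard normalisation that makes indel positions in
#' repetitive context unambiguous. Deletions are keyed by the position of
#' the first deleted base; insertions by the anchor base immediately 5' of
#' the inserted sequence (position 0 means insertion before the first
#' base). The operation is idempotent.
#'
#' @param ref Reference sequence (character scalar).
#' @param pos Indel position (see above).
#' @param type `"ins"` or `"del"`.
#' @param allele Inserted sequence (for `ins`) or deleted sequence (for
#'   `del`; must match the reference at `pos`).
#' @return List with normalised `pos` and `allele`.
#' @export
left_align_indel <- function(ref, pos, type, allele) {
  rc <- strsplit(ref, "")[[1L]]
  if (type == "del") {
    L <- nchar(allele)
    stopifnot(substr(ref, pos, pos + L - 1L) == allele)
    while (pos > 1L && rc[pos - 1L] == rc[pos + L - 1L]) pos <- pos - 1L
    allele <- substr(ref, pos, pos + L - 1L)
  } else if (type == "ins") {
    s <- strsplit(allele, "")[[1L]]
    while (pos >= 1L && rc[pos] == s[length(s)]) {
      s <- c(rc[pos], s[-length(s)])
      pos <- pos - 1L
    }
    allele <- paste(s, collapse = "")
  } else stop("unknown indel type: ", type)
  list(pos = as.integer(pos), allele = allele)
}

#' Call insertion/deletion alleles from amplicon alignments
#'
#' Extracts every I/D CIGAR operation inside the target window from reads
#' aligned to the amplicon reference, left-aligns each indel
#' ([left_align_indel()]), and aggregates identical (position, type,
#' allele) records into an allele table with per-allele frequencies.
#' Substitution errors never create indel rows because only CIGAR I/D
#' operations are counted. Alleles below `min_freq` (default 0.5%, a
#' guard against sequencing-error artifacts when alignments come from an
#' error-prone aligner) are dropped from the table; the edited fraction is
#' computed before that filter.
#'
#' @param alignments `GAlignments`, SAM/BAM path, or simulator data.frame
#'   (see [count_junction_reads()] for accepted forms).
#' @param reference Amplicon reference sequence (character scalar).
#' @param window Optional `c(start, end)` restricting calls to a target
#'   window; default the whole reference.
#' @param min_freq Minimum reported allele frequency.
#' @param cut Optional cut-site coordinate stored as metadata (for SpCas9,
#'   between protospacer positions 17 and 18, 3 nt 5' of the PAM).
#' @return An object of class `IndelTable`: list with `rows` (data.frame:
#'   `position`, `type`, `allele`, `length`, `count`, `frequency`),
#'   `n_reads`, `edited_fraction`, `window`, `cut`.
#' @export
call_indels <- function(alignments, reference, window = NULL,
                        min_freq = 0.005, cut = NULL) {
  ga <- as_galignments(alignments)
  if (is.null(window)) window <- c(1L, nchar(reference))
  n_reads <- length(ga)
  if (n_reads == 0L) {
    warning("no aligned reads")
    return(structure(list(
      rows = data.frame(position = integer(), type = character(),
                        allele = character(), length = integer(),
                        count = integer(), frequency = numeric()),
      n_reads = 0L, edited_fraction = NA_real_, window = window, cut = cut),
      class = "IndelTable"))
  }
  cig <- GenomicAlignments::cigar(ga)
  starts <- GenomicAlignments::start(ga)
  seqs <- as.character(S4Vectors::mcols(ga)$seq)
  ops_l <- GenomicAlignments::explodeCigarOps(cig)
  lens_l <- GenomicAlignments::explodeCigarOpLengths(cig)
  recs <- vector("list", n_reads)
  edited <- logical(n_reads)
  for (i in seq_len(n_reads)) {
    ops <- ops_l[[i]]; lens <- lens_l[[i]]
    rpos <- starts[i]; qpos <- 1L
    out <- list()
    for (j in seq_along(ops)) {
      op <- ops[j]; L <- lens[j]
      if (op %in% c("M", "=", "X")) {
        rpos <- rpos + L; qpos <- qpos + L
      } else if (op == "I") {
        anchor <- rpos - 1L
        allele <- substr(seqs[i], qpos, qpos + L - 1L)
        la <- left_align_indel(reference, anchor, "ins", allele)
        if (la$pos >= window[1L] - 1L && la$pos <= window[2L])
          out[[length(out) + 1L]] <-
            data.frame(position = la$pos, type = "ins", allele = la$allele,
                       length = L)
        qpos <- qpos + L
      } else if (op == "D") {
        allele <- substr(reference, rpos, rpos + L - 1L)
        la <- left_align_indel(reference, rpos, "del", allele)
        if (la$pos <= window[2L] && la$pos + L - 1L >= window[1L])
          out[[length(out) + 1L]] <-
            data.frame(position = la$pos, type = "del", allele = la$allele,
                       length = L)
        rpos <- rpos + L
      } else if (op == "N") {
        rpos <- rpos + L   # splice skip, never an indel allele
      } else if (op == "S") {
        qpos <- qpos + L
      } else if (op == "H" || op == "P") {
        # consumes neither
      }
    }
    if (length(out)) {
      recs[[i]] <- do.call(rbind, out)
      edited[i] <- TRUE
    }
  }
  all_rec <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(all_rec)) {
    rows <- data.frame(position = integer(), type = character(),
                       allele = character(), length = integer(),
                       count = integer(), frequency = numeric())
  } else {
    agg <- stats::aggregate(
      list(count = rep(1L, nrow(all_rec))),
      by = all_rec[, c("position", "type", "allele", "length")], FUN = sum)
    agg$frequency <- agg$count / n_reads
    agg <- agg[agg$frequency >= min_freq, , drop = FALSE]
    rows <- agg[order(-agg$count), , drop = FALSE]
    rownames(rows) <- NULL
  }
  structure(list(rows = rows, n_reads = n_reads,
                 edited_fraction = mean(edited), window = window,
                 cut = cut),
            class = "IndelTable")
}

#' @export
print.IndelTable <- function(x, ...) {
  cat(sprintf("IndelTable: %d reads, edited fraction %.3f\n",
              x$n_reads, x$edited_fraction))
  if (nrow(x$rows)) print(utils::head(x$rows, 10L))
  invisible(x)
}

#' Write an indel table as TSV
#' @param x An `IndelTable`.
#' @param path Output path.
#' @param provenance Optional '#'-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_indel_table <- function(x, path, provenance = character()) {
  write_tsv_prov(x$rows, path,
                 c(provenance,
                   sprintf("n_reads=%d edited_fraction=%.6f", x$n_reads,
                           x$edited_fraction)))
}

#' Classify sgRNA cutting strength from its editing rate
#'
#' A guide is called strong when its indel frequency strictly exceeds the
#' threshold (default 20%, the conventional bar separating efficient from
#' inefficient guides).
#'
#' @param edited_fraction Fraction of reads carrying at least one indel.
#' @param threshold Strength threshold (default 0.20).
#' @return `"strong"` or `"weak"`.
#' @export
classify_sgrna <- function(edited_fraction, threshold = 0.20) {
  stopifnot(edited_fraction >= 0, edited_fraction <= 1)
  if (edited_fraction > threshold) "strong" else "weak"
}

#' Rank correlation between editing efficiency and exon skipping
#'
#' Spearman correlation between per-guide genomic indel frequencies and
#' exon-skipping fractions. Pairs with a missing member (e.g. indels not
#' determined, or skip bands too faint to quantify) are dropped and the n
#' actually used is reported.
#'
#' @param edited_fraction,skip_fraction Numeric vectors of equal length;
#'   `NA`s allowed.
#' @return List with `coefficient` (Spearman rho), `n` (complete pairs
#'   used) and `n_dropped`.
#' @export
correlate_editing_skipping <- function(edited_fraction, skip_fraction) {
  stopifnot(length(edited_fraction) == length(skip_fraction))
  ok <- stats::complete.cases(edited_fraction, skip_fraction)
  if (sum(ok) < 3L) stop("insufficient data: need >= 3 complete pairs")
  list(coefficient = stats::cor(edited_fraction[ok], skip_fraction[ok],
                                method = "spearman"),
       n = sum(ok), n_dropped = sum(!ok))
}

#' Align raw amplicon reads to a reference (convenience)
#'
#' Global pairwise alignment of each read against the amplicon reference,
#' returning alignment records consumable by [call_indels()]. Scoring is
#' pinned for reproducibility: match +2, mismatch -3, and an affine gap
#' cost of 5 for the first gapped base plus 1 per additional base.
#' Intended for small amplicon panels; aligned SAM input is the primary
#' path.
#'
#' @param reads Character vector or `DNAStringSet` of reads.
#' @param reference Amplicon reference sequence (character scalar).
#' @return `data.frame` of SAM-field alignment records.
#' @export
align_amplicon_reads <- function(reads, reference) {
  reads <- as.character(reads)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  cigars <- vapply(reads, function(rd) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = rd, subject = reference, type = "global",
      substitutionMatrix = mat, gapOpening = 4, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    op <- ifelse(p == "-", "D", ifelse(s == "-", "I", "M"))
    r <- rle(op)
    paste0(r$lengths, r$values, collapse = "")
  }, character(1))
  data.frame(qname = names(reads), flag = 0L, rname = "amplicon",
             pos = 1L, mapq = 60L, cigar = unname(cigars),
             seq = unname(reads),
             qual = vapply(reads, function(x) strrep("I", nchar(x)),
                           character(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}
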
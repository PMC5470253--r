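#' Count junction-spanning reads for one gene
#'
#' Walks the gapped (N-containing) alignments over the gene's chromosome
#' and counts, for every pair of exons (i, j), the reads whose aligned
#' blocks end exactly at exon i's last base and resume exactly at exon j's
#' first base, with at least `min_overhang` aligned nt on both sides of
#' the junction. A read that spans several junctions increments each.
#' Junctions whose coordinates match no annotated exon boundary are
#' collected under `"novel"` keys (`novel:<donor_end>-<acceptor_start>`)
#' and reported, never dropped: deletion-derived fusion transcripts show
#' up here.
#'
#' @param alignments A `GAlignments` object (see [read_alignments()]), a
#'   path to a SAM/BAM file, or a simulator `alignments` data.frame.
#' @param gene A [GeneModel].
#' @param min_overhang Minimum aligned nt on each side of the junction
#'   (default 6).
#' @param dedup If `TRUE`, reads with identical (chrom, start, CIGAR) are
#'   counted once (single-end approximation of duplicate-pair removal).
#' @param sample_id Label stored in the result.
#' @return An object of class `JunctionCounts`: list with `sample_id`,
#'   `counts` (named integer vector, names `"<donor>-<acceptor>"` or
#'   `"novel:..."`), and `n_total_gene_reads`.
#' @export
count_junction_reads <- function(alignments, gene, min_overhang = 6L,
                                 dedup = FALSE, sample_id = "sample") {
  ga <- as_galignments(alignments)
  ga <- ga[as.character(GenomicAlignments::seqnames(ga)) == gene$chrom]
  if (length(ga) == 0L) {
    warning("no mapped reads on the gene's chromosome")
    return(structure(list(sample_id = sample_id,
                          counts = stats::setNames(integer(), character()),
                          n_total_gene_reads = 0L),
                     class = "JunctionCounts"))
  }
  if (dedup) {
    key <- paste(GenomicAlignments::start(ga),
                 GenomicAlignments::cigar(ga), sep = "|")
    ga <- ga[!duplicated(key)]
  }
  ex <- gene$exons
  # vectorised: per-read aligned blocks from the CIGARs, then junction
  # boundaries from consecutive block pairs within each read
  irl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    GenomicAlignments::cigar(ga), pos = GenomicAlignments::start(ga),
    ops = c("M", "=", "X"), reduce.ranges = TRUE)
  nblk <- S4Vectors::elementNROWS(irl)
  flat <- unlist(irl, use.names = FALSE)
  bs <- IRanges::start(flat); be <- IRanges::end(flat)
  read_id <- rep.int(seq_along(irl), nblk)
  n_gene <- sum(vapply(split(seq_along(read_id), read_id), function(ii)
    max(be[ii]) >= min(ex$start) && min(bs[ii]) <= max(ex$end), logical(1)))
  left <- which(read_id[-length(read_id)] == read_id[-1L])
  right <- left + 1L
  ok <- (be[left] - bs[left] + 1L) >= min_overhang &
    (be[right] - bs[right] + 1L) >= min_overhang
  donor_end <- be[left][ok]; acc_start <- bs[right][ok]
  di <- match(donor_end, ex$end); ai <- match(acc_start, ex$start)
  annotated <- !is.na(di) & !is.na(ai) &
    ifelse(is.na(di) | is.na(ai), FALSE, ex$label[di] < ex$label[ai])
  keys <- ifelse(annotated,
                 paste0(ex$label[di], "-", ex$label[ai]),
                 paste0("novel:", donor_end, "-", acc_start))
  tab <- table(keys)
  cnt <- stats::setNames(as.integer(tab), names(tab))
  structure(list(sample_id = sample_id, counts = cnt,
                 n_total_gene_reads = n_gene),
            class = "JunctionCounts")
}

# Internal: coerce the accepted alignment inputs to GAlignments.
as_galignments <- function(x) {
  if (methods::is(x, "GAlignments")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_alignments(x))
  if (is.data.frame(x)) {
    # simulator records: route through a temporary SAM for a single code path
    sl <- stats::setNames(
      vapply(split(x$pos + GenomicAlignments::cigarWidthAlongReferenceSpace(
        x$cigar), x$rname), max, numeric(1)) + 500,
      unique(x$rname)[order(unique(x$rname))])
    tmp <- tempfile(fileext = ".sam")
    on.exit(unlink(tmp))
    write_sam(x, tmp, sl)
    return(read_alignments(tmp))
  }
  stop("unsupported alignment input")
}

#' Junction counts as a data.frame
#' @param x A `JunctionCounts`.
#' @param row.names,optional,... Ignored (standard generic arguments).
#' @return data.frame with `sample`, `donor`, `acceptor`, `count`
#'   (`donor`/`acceptor` are `NA` for novel junctions, which keep their
#'   coordinate key in `key`).
#' @exportS3Method base::as.data.frame
#' @export
as.data.frame.JunctionCounts <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  keys <- names(x$counts)
  novel <- startsWith(keys, "novel:")
  donor <- acceptor <- rep(NA_integer_, length(keys))
  if (any(!novel)) {
    parts <- strsplit(keys[!novel], "-", fixed = TRUE)
    donor[!novel] <- as.integer(vapply(parts, `[`, character(1), 1L))
    acceptor[!novel] <- as.integer(vapply(parts, `[`, character(1), 2L))
  }
  data.frame(sample = x$sample_id, key = keys, donor = donor,
             acceptor = acceptor, count = as.integer(x$counts),
             row.names = NULL)
}

#' @export
print.JunctionCounts <- function(x, ...) {
  cat(sprintf("JunctionCounts '%s': %d junction(s), %d gene reads\n",
              x$sample_id, length(x$counts), x$n_total_gene_reads))
  if (length(x$counts)) print(x$counts)
  invisible(x)
}

# Internal: junction count lookup, absent keys read as 0.
jx_count <- function(counts, donor, acceptor) {
  key <- paste0(donor, "-", acceptor)
  v <- counts$counts[key]
  if (is.na(v)) 0L else as.integer(v)
}

#' Inclusion and total junction-read counts for a cassette exon
#'
#' For a cassette `mid` flanked by `up` and `down`, the inclusion count is
#' e(up,mid) + e(mid,down) (both inclusion junctions contribute) and the
#' total adds the exclusion junction e(up,down).
#'
#' @param counts A `JunctionCounts`.
#' @param cassette Length-3 integer vector `c(up, mid, down)` of exon
#'   labels.
#' @return List with `x_inclusion` and `m_total`.
#' @export
inclusion_counts <- function(counts, cassette) {
  stopifnot(length(cassette) == 3L)
  x <- jx_count(counts, cassette[1L], cassette[2L]) +
    jx_count(counts, cassette[2L], cassette[3L])
  list(x_inclusion = x,
       m_total = x + jx_count(counts, cassette[1L], cassette[3L]))
}

#' Percent spliced-in (PSI) of a cassette exon from junction reads
#'
#' Computes (e(up,mid) + e(mid,down)) / (e(up,mid) + e(mid,down) +
#' e(up,down)): the fraction of junction evidence supporting inclusion of
#' the cassette exon. Inclusion is supported by two junctions and
#' exclusion by one; the statistic is used verbatim in this form rather
#' than length-normalised.
#'
#' @inheritParams inclusion_counts
#' @return The PSI as a fraction in `[0, 1]`, or `NA` (with a warning)
#'   when no informative reads exist.
#' @examples
#' jc <- structure(list(sample_id = "s",
#'   counts = c("1-2" = 64, "2-3" = 64, "1-3" = 72),
#'   n_total_gene_reads = 200L), class = "JunctionCounts")
#' compute_psi(jc, c(1, 2, 3))  # 0.64
#' @export
compute_psi <- function(counts, cassette) {
  ic <- inclusion_counts(counts, cassette)
  if (ic$m_total == 0L) {
    warning("no informative reads for cassette ",
            paste(cassette, collapse = "-"))
    return(NA_real_)
  }
  ic$x_inclusion / ic$m_total
}

#' Geometry-corrected cassette inclusion weight from junction reads
#'
#' The junction-count PSI statistic ([compute_psi()]) counts two
#' junctions for inclusion but one for exclusion, and reads land on a
#' junction at a rate inversely proportional to the isoform's mRNA
#' length, so as an estimator of the underlying isoform mixture it is
#' biased. This estimator corrects both effects: inclusion evidence is
#' averaged over its two junctions and each side is weighted by its
#' isoform's number of read start positions,
#' \deqn{\hat w = \frac{(x/2)\,(L_{in}-r+1)}
#'                     {(x/2)\,(L_{in}-r+1) + e\,(L_{ex}-r+1)}}
#' with x the inclusion-junction reads, e the exclusion-junction reads,
#' r the read length and L the isoform mRNA lengths. It converges to the
#' true inclusion-isoform fraction for reads placed uniformly along each
#' isoform (junctions away from the mRNA ends).
#'
#' @inheritParams inclusion_counts
#' @param gene The [GeneModel] (for exon lengths).
#' @param read_length Read length used in the experiment/simulation.
#' @param inclusion_length,exclusion_length Override the isoform mRNA
#'   lengths; defaults are the full exon set with / without the cassette.
#' @return Estimated inclusion-isoform fraction in `[0, 1]`, `NA` when no
#'   informative reads exist.
#' @export
estimate_inclusion_weight <- function(counts, gene, cassette, read_length,
                                      inclusion_length = NULL,
                                      exclusion_length = NULL) {
  ic <- inclusion_counts(counts, cassette)
  if (ic$m_total == 0L) return(NA_real_)
  lens <- exon_lengths(gene)
  if (is.null(inclusion_length)) inclusion_length <- sum(lens)
  if (is.null(exclusion_length))
    exclusion_length <- inclusion_length - lens[[as.character(cassette[2L])]]
  e_excl <- ic$m_total - ic$x_inclusion
  a <- (ic$x_inclusion / 2) * (inclusion_length - read_length + 1)
  b <- e_excl * (exclusion_length - read_length + 1)
  a / (a + b)
}

#' Inclusion-isoform weight that yields a target junction-count PSI
#'
#' Inverse of the junction-count PSI statistic under uniform read
#' placement: given a target value of the printed statistic (e.g. a
#' measured % exon inclusion), returns the inclusion-isoform mixture
#' fraction at which the statistic's expectation equals that target.
#' Used to parameterise [simulate_junction_reads()] so a simulated clone
#' reproduces a measured PSI.
#'
#' @param gene A [GeneModel].
#' @param cassette `c(up, mid, down)` exon labels.
#' @param psi Target PSI (fraction).
#' @param read_length Read length.
#' @return Inclusion-isoform weight in `[0, 1]`.
#' @export
inclusion_weight_for_psi <- function(gene, cassette, psi, read_length) {
  lens <- exon_lengths(gene)
  l_in <- sum(lens)
  l_ex <- l_in - lens[[as.character(cassette[2L])]]
  a <- 1 / (l_in - read_length + 1)   # per-junction read rate, inclusion
  b <- 1 / (l_ex - read_length + 1)   # exclusion
  (b * psi) / (2 * a * (1 - psi) + b * psi)
}

#' Acceptor-usage fractions of a donor exon
#'
#' Normalises the counts of all junctions leaving one donor exon, giving
#' the relative usage of each downstream splice acceptor (e.g. the
#' exon 2-4 / 2-5 / 2-6 / 2-7 ladder of promiscuous multi-exon skipping).
#'
#' @param counts A `JunctionCounts`.
#' @param donor Donor exon label.
#' @return Named numeric vector of fractions over acceptor labels,
#'   summing to 1; `NA`-named entries are never produced (novel junctions
#'   are excluded). Errors with "no informative reads" when nothing leaves
#'   the donor.
#' @export
donor_usage_fractions <- function(counts, donor) {
  df <- as.data.frame(counts)
  df <- df[!is.na(df$donor) & df$donor == donor, , drop = FALSE]
  tot <- sum(df$count)
  if (tot == 0L) stop("no informative reads leaving donor exon ", donor)
  stats::setNames(df$count / tot, df$acceptor)[order(df$acceptor)]
}

#' Percent reduction in gene expression, clone versus parent
#'
#' Computes `100 * (1 - mean(clone) / mean(parent))` from per-replicate
#' normalised gene-level read counts. Negative values indicate an
#' increase. This is the statistic behind "apparent mRNA levels reduced by
#' X%" comparisons, relevant because NMD of frameshifted transcripts
#' predicts a much larger reduction than is observed when the exon is
#' skipped instead.
#'
#' @param clone_counts,parent_counts Numeric vectors of per-replicate
#'   totals (at least one each).
#' @return Percent reduction (scalar).
#' @export
expression_change <- function(clone_counts, parent_counts) {
  stopifnot(length(clone_counts) >= 1L, length(parent_counts) >= 1L)
  mp <- mean(parent_counts)
  if (mp <= 0) stop("undefined reduction: parental mean is not positive")
  100 * (1 - mean(clone_counts) / mp)
}

#' Write junction counts as TSV
#' @param counts A `JunctionCounts`.
#' @param path Output path.
#' @param provenance Optional '#'-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_junction_counts <- function(counts, path, provenance = character()) {
  write_tsv_prov(as.data.frame(counts), path, provenance)
}
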
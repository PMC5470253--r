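#' Spliced transcript sequence of an isoform
#'
#' @param gm A [GeneModel].
#' @param isoform Integer vector of exon labels (default: all exons).
#' @param genome Chromosome sequence (character scalar).
#' @return mRNA sequence (character scalar), exons concatenated 5' to 3'.
#' @export
transcript_sequence <- function(gm, genome, isoform = gm$exons$label) {
  idx <- match(isoform, gm$exons$label)
  if (anyNA(idx)) stop("unknown exon label(s)")
  paste(vapply(idx, function(i)
    substr(genome, gm$exons$start[i], gm$exons$end[i]), character(1)),
    collapse = "")
}

#' Reading-frame consequence of skipping cassette exons
#'
#' Sums the lengths of the skipped exons and applies the mod-3 rule: a
#' skip whose total length is divisible by 3 preserves the downstream
#' reading frame (in-frame skip, e.g. a 213-nt or 228-nt cassette), while
#' any other length shifts it. For a frameshifting skip, if the genome
#' sequence is supplied the transcript downstream of the skip junction is
#' scanned for the first ATG that lies in the annotated reading frame of
#' the full-length transcript: translation restarting there yields the
#' annotated downstream protein frame (a severely N-terminally truncated
#' protein). No Kozak-context scoring is applied.
#'
#' @param gm A [GeneModel].
#' @param skipped Integer vector of skipped exon labels; must be internal
#'   exons (skipping a terminal exon is not a cassette skip).
#' @param genome Optional chromosome sequence enabling the downstream-ATG
#'   scan.
#' @param coding_start 1-based offset of the translation start within the
#'   coding start exon (default 1 in `gm$coding_start_exon`, or exon 1).
#' @return An object of class `FrameReport`: list with `skipped`,
#'   `skipped_length`, `in_frame`, `downstream_start` (`NULL`, or list
#'   with `exon`, `offset`, `transcript_pos`).
#' @export
frame_report <- function(gm, skipped, genome = NULL, coding_start = 1L) {
  ex <- gm$exons
  idx <- match(skipped, ex$label)
  if (anyNA(idx)) stop("unknown exon label(s)")
  if (any(idx == 1L) || any(idx == nrow(ex)))
    stop("not a cassette skip: terminal exon")
  lens <- ex$end - ex$start + 1L
  skipped_length <- sum(lens[idx])
  in_frame <- skipped_length %% 3L == 0L
  downstream_start <- NULL
  if (!in_frame && !is.null(genome)) {
    # transcript coordinates on the FULL transcript; annotated frame anchors
    # at the coding start.
    first <- c(1L, utils::head(cumsum(lens), -1L) + 1L)
    cds_exon <- if (!is.null(gm$coding_start_exon)) gm$coding_start_exon
                else ex$label[1L]
    cds_pos <- first[match(cds_exon, ex$label)] + coding_start - 1L
    junction <- max(first[idx] + lens[idx] - 1L)  # last skipped base
    mrna <- transcript_sequence(gm, genome)
    hits <- as.integer(
      Biostrings::start(Biostrings::matchPattern("ATG",
                                                 Biostrings::DNAString(mrna))))
    hits <- hits[hits > junction & (hits - cds_pos) %% 3L == 0L]
    if (length(hits)) {
      q <- min(hits)
      ei <- max(which(first <= q))
      downstream_start <- list(exon = ex$label[ei], offset = q - first[ei] + 1L,
                               transcript_pos = q)
    }
  }
  structure(list(skipped = skipped, skipped_length = skipped_length,
                 in_frame = in_frame, downstream_start = downstream_start),
            class = "FrameReport")
}

#' @export
print.FrameReport <- function(x, ...) {
  cat(sprintf("Skip exon(s) %s: %d nt, %s\n",
              paste(x$skipped, collapse = "+"), x$skipped_length,
              if (x$in_frame) "in frame" else "frameshift"))
  if (!is.null(x$downstream_start))
    cat(sprintf("  first in-frame downstream ATG: exon %d, offset %d\n",
                x$downstream_start$exon, x$downstream_start$offset))
  invisible(x)
}

#' Predict the RT-PCR product size for an isoform
#'
#' Product length on the cDNA of a given isoform: the forward-primer
#' exon's remaining length from the primer start, plus the full lengths of
#' the isoform's exons between the two primer exons, plus the
#' reverse-primer exon's length up to the primer end. The arithmetic is in
#' exon-label space, not genomic space, so the same prediction serves any
#' isoform including deletion-derived ones. Returns `NA` ("no product")
#' when either primer's exon is absent from the isoform.
#'
#' @param gm A [GeneModel].
#' @param isoform Integer vector of exon labels present in the transcript.
#' @param primers A [PrimerPair]; each primer must lie fully inside one
#'   exon.
#' @return Product length in nt, or `NA_integer_` when there is no
#'   product.
#' @examples
#' fx <- build_fixture("kras")
#' predict_amplicon_size(fx$model, c(1, 2, 3), fx$primers)  # 331
#' predict_amplicon_size(fx$model, c(1, 3), fx$primers)     # 209
#' @export
predict_amplicon_size <- function(gm, isoform, primers) {
  ex <- gm$exons
  exon_of <- function(interval) {
    i <- which(ex$start <= interval[1L] & interval[2L] <= ex$end)
    if (length(i) != 1L) stop("unsupported primer placement: ",
                              "primer must lie fully inside one exon")
    i
  }
  fi <- exon_of(primers$forward)
  ri <- exon_of(primers$reverse)
  if (fi >= ri) stop("unsupported primer placement: reverse primer must ",
                     "lie in a downstream exon")
  if (!(ex$label[fi] %in% isoform) || !(ex$label[ri] %in% isoform))
    return(NA_integer_)
  mid <- isoform[isoform > ex$label[fi] & isoform < ex$label[ri]]
  mid_len <- if (length(mid)) sum(exon_lengths(gm, mid)) else 0L
  as.integer((ex$end[fi] - primers$forward[1L] + 1L) + mid_len +
               (primers$reverse[2L] - ex$start[ri] + 1L))
}

#' Interpret a genomic deletion allele
#'
#' Annotates a deletion interval against a gene model: lesion length,
#' exons removed entirely, the context of each breakpoint (intronic or
#' exonic, and within which intron/exon), and a predicted transcript.
#' When both breakpoints are intronic, the nearest surviving upstream exon
#' is predicted to splice directly to the nearest surviving downstream
#' exon (a stated simplification -- splice-site strength is not
#' modelled). When a breakpoint is exonic, the prediction is a fusion
#' transcript retaining the upstream segment joined to the surviving
#' downstream remainder (e.g. an intron stub fused to a truncated exon).
#' A deletion entirely inside one intron leaves the transcript unchanged.
#'
#' @param gene A [GeneModel].
#' @param start,end Deletion breakpoints, 1-based inclusive; must overlap
#'   the gene locus.
#' @return An object of class `DeletionAllele`: list with `gene_id`,
#'   `start`, `end`, `length`, `removed_exons`, `context_5p`,
#'   `context_3p` (each a list: `kind` = `"intronic"`/`"exonic"`/
#'   `"flanking"`, `unit` = intron/exon label), `predicted_junction`
#'   (`c(upstream, downstream)` exon labels or `NULL`), and
#'   `predicted_transcript` (human-readable description).
#' @examples
#' p65 <- build_fixture("p65")$model
#' interpret_deletion(p65, 400, 2667)  # removes exons 5-7, exon 4-8 splice
#' @export
interpret_deletion <- function(gene, start, end) {
  s <- as.integer(start); e <- as.integer(end)
  stopifnot(s >= 1L, s <= e)
  ex <- gene$exons
  locus <- c(min(ex$start), max(ex$end))
  if (e < locus[1L] || s > locus[2L]) stop("deletion outside gene")
  removed <- ex$label[ex$start >= s & ex$end <= e]
  intr <- gene_introns(gene)
  ctx <- function(pos) {
    i <- which(ex$start <= pos & pos <= ex$end)
    if (length(i)) return(list(kind = "exonic", unit = ex$label[i]))
    j <- which(intr$start <= pos & pos <= intr$end)
    if (length(j)) return(list(kind = "intronic", unit = intr$after_label[j]))
    list(kind = "flanking", unit = NA_integer_)
  }
  c5 <- ctx(s); c3 <- ctx(e)
  up <- ex$label[ex$end < s]      # exons fully upstream (intact)
  down <- ex$label[ex$start > e]  # exons fully downstream (intact)
  predicted_junction <- NULL
  if (c5$kind != "exonic" && c3$kind != "exonic") {
    if (length(removed) == 0L) {
      desc <- "transcript unchanged (intronic deletion, no exon removed)"
      if (length(up) && length(down))
        predicted_junction <- c(max(up), min(down))
    } else if (length(up) && length(down)) {
      predicted_junction <- c(max(up), min(down))
      desc <- sprintf("exon %d-%d splice product (exons %s deleted)",
                      predicted_junction[1L], predicted_junction[2L],
                      paste(removed, collapse = ", "))
    } else {
      desc <- "terminal exons removed; no simple splice prediction"
    }
  } else {
    left <- if (c5$kind == "exonic")
      sprintf("5' part of exon %d", c5$unit)
    else sprintf("5' end of intron %d stub", c5$unit)
    right <- if (c3$kind == "exonic")
      sprintf("3' remainder of exon %d", c3$unit)
    else if (length(down)) sprintf("exon %d", min(down)) else "gene end"
    desc <- sprintf("fusion transcript: %s joined to %s", left, right)
  }
  structure(list(gene_id = gene$gene_id, start = s, end = e,
                 length = e - s + 1L, removed_exons = removed,
                 context_5p = c5, context_3p = c3,
                 predicted_junction = predicted_junction,
                 predicted_transcript = desc),
            class = "DeletionAllele")
}

#' @export
print.DeletionAllele <- function(x, ...) {
  cat(sprintf("%s deletion %d-%d (%d bp)\n", x$gene_id, x$start, x$end,
              x$length))
  cat(sprintf("  removed exons: %s\n",
              if (length(x$removed_exons))
                paste(x$removed_exons, collapse = ", ") else "none"))
  cat("  ", x$predicted_transcript, "\n", sep = "")
  invisible(x)
}
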
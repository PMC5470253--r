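#' Construct a gene model
#'
#' A `GeneModel` describes the ordered exon structure of a single gene on a
#' (toy or real) chromosome. Exons carry integer labels that need not start
#' at 1: a model may describe only the exons relevant to an experiment
#' (e.g. exons 2--7 of a locus). Introns are derived as the maximal gaps
#' between consecutive exons.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome (or amplicon/contig) name.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with columns `label` (strictly increasing
#'   integers), `start`, `end` (1-based inclusive genomic coordinates).
#' @param coding_start_exon Optional integer label of the exon in which
#'   translation starts.
#' @return An object of class `GeneModel`.
#' @export
GeneModel <- function(gene_id, chrom, strand = "+", exons,
                      coding_start_exon = NULL) {
  exons <- as.data.frame(exons)[, c("label", "start", "end")]
  exons$label <- as.integer(exons$label)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  gm <- structure(
    list(gene_id = as.character(gene_id), chrom = as.character(chrom),
         strand = strand, exons = exons,
         coding_start_exon = coding_start_exon),
    class = "GeneModel")
  validate_gene_model(gm)
  gm
}

#' Validate GeneModel invariants
#'
#' Checks exon ordering, non-overlap, positive widths and strictly
#' increasing labels. Called by every constructor/loader.
#'
#' @param gm A `GeneModel`.
#' @return `gm`, invisibly; stops with "malformed model" otherwise.
#' @export
validate_gene_model <- function(gm) {
  ex <- gm$exons
  if (nrow(ex) < 1L) stop("malformed model: no exons")
  if (any(ex$end < ex$start)) stop("malformed model: exon end < start")
  if (!gm$strand %in% c("+", "-")) stop("malformed model: bad strand")
  if (nrow(ex) > 1L) {
    if (any(diff(ex$start) <= 0) || any(ex$start[-1L] <= ex$end[-nrow(ex)]))
      stop("malformed model: overlapping or unsorted exons")
    # labels strictly increase in transcription order (5' to 3')
    dl <- if (gm$strand == "+") diff(ex$label) else -diff(ex$label)
    if (any(dl <= 0))
      stop("malformed model: exon labels not strictly increasing 5'->3'")
  }
  if (anyDuplicated(ex$label)) stop("malformed model: duplicate exon labels")
  invisible(gm)
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s%s), %d exons\n", x$gene_id, x$chrom,
              x$strand, nrow(x$exons)))
  print(x$exons)
  invisible(x)
}

#' Exon lengths of a gene model
#'
#' @param gm A `GeneModel`.
#' @param labels Optional subset of exon labels.
#' @return Named integer vector of exon lengths (nt), names are labels.
#' @export
exon_lengths <- function(gm, labels = NULL) {
  ex <- gm$exons
  if (!is.null(labels)) {
    idx <- match(labels, ex$label)
    if (anyNA(idx)) stop("unknown exon label(s): ",
                         paste(labels[is.na(idx)], collapse = ", "))
    ex <- ex[idx, , drop = FALSE]
  }
  stats::setNames(ex$end - ex$start + 1L, ex$label)
}

#' Derived introns of a gene model
#'
#' @param gm A `GeneModel`.
#' @return `data.frame` with `after_label` (upstream exon label), `start`,
#'   `end` of each intron; zero rows for single-exon models.
#' @export
gene_introns <- function(gm) {
  ex <- gm$exons
  if (nrow(ex) < 2L)
    return(data.frame(after_label = integer(), start = integer(),
                      end = integer()))
  data.frame(after_label = ex$label[-nrow(ex)],
             start = ex$end[-nrow(ex)] + 1L,
             end = ex$start[-1L] - 1L)
}

#' Load a gene model from GTF or BED12
#'
#' GTF files are matched on the `gene_id` attribute of `exon` records; all
#' exon records for the gene (across transcripts) are merged by coordinate.
#' BED12 files are matched on the `name` column and expanded from their
#' blocks. Minus-strand records are accepted; exon labels are assigned in
#' transcription order (5' to 3'), i.e. by decreasing coordinate on the
#' minus strand, unless the GTF carries `exon_number` attributes.
#'
#' @param path Path to a `.gtf`/`.gff` or `.bed` file.
#' @param gene_id Gene to extract.
#' @param format Override the extension-based format guess
#'   (`"gtf"` or `"bed"`).
#' @return A `GeneModel`.
#' @export
load_gene_model <- function(path, gene_id, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("bed", "bed12")) "bed" else "gtf"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    gr <- gr[!is.na(gr$name) & gr$name == gene_id]
    if (length(gr) == 0L) stop("gene not found: ", gene_id)
    blocks <- gr$blocks[[1L]]
    ex_gr <- GenomicRanges::shift(
      GenomicRanges::GRanges(GenomicRanges::seqnames(gr)[1L], blocks,
                             strand = GenomicRanges::strand(gr)[1L]),
      GenomicRanges::start(gr)[1L] - 1L)
    strand <- as.character(GenomicRanges::strand(gr))[1L]
    labels <- NULL
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    keep <- !is.na(gr$gene_id) & gr$gene_id == gene_id &
      (is.na(gr$type) | gr$type == "exon")
    ex_gr <- gr[keep]
    if (length(ex_gr) == 0L) stop("gene not found: ", gene_id)
    strand <- as.character(GenomicRanges::strand(ex_gr))[1L]
    labels <- if (!is.null(ex_gr$exon_number))
      as.integer(as.character(ex_gr$exon_number)) else NULL
  }
  if (strand == "*") strand <- "+"
  st <- GenomicRanges::start(ex_gr)
  en <- GenomicRanges::end(ex_gr)
  o <- order(st)
  st <- st[o]; en <- en[o]
  if (anyDuplicated(cbind(st, en)))
    stop("malformed model: duplicate exon coordinates")
  if (is.null(labels)) {
    # transcription order: 5'->3' along the strand
    labels <- if (strand == "+") seq_along(st) else rev(seq_along(st))
  } else {
    labels <- labels[o]
  }
  GeneModel(gene_id, as.character(GenomicRanges::seqnames(ex_gr))[1L],
            strand, data.frame(label = labels, start = st, end = en))
}

#' Write a gene model as GTF
#'
#' Emits one `exon` record per exon with `gene_id`, `transcript_id` (equal
#' to the gene id) and `exon_number` attributes, so a written model
#' round-trips through [load_gene_model()] unchanged.
#'
#' @param gm A `GeneModel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gm, path) {
  ex <- gm$exons
  gr <- GenomicRanges::GRanges(
    gm$chrom, IRanges::IRanges(ex$start, ex$end), strand = gm$strand,
    type = "exon", source = "skipquant",
    gene_id = gm$gene_id, transcript_id = gm$gene_id,
    exon_number = as.character(ex$label))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Reflect a gene model onto the opposite strand
#'
#' Maps every coordinate x to `chrom_length - x + 1` and flips the strand,
#' preserving exon labels (which stay in transcription order). Used to
#' exercise minus-strand handling without minus-strand fixtures.
#'
#' @param gm A `GeneModel`.
#' @param chrom_length Length of the chromosome to reflect within.
#' @return A `GeneModel` on the opposite strand.
#' @export
reflect_gene_model <- function(gm, chrom_length) {
  ex <- gm$exons
  new_ex <- data.frame(label = ex$label,
                       start = chrom_length - ex$end + 1L,
                       end = chrom_length - ex$start + 1L)
  GeneModel(gm$gene_id, gm$chrom, if (gm$strand == "+") "-" else "+",
            new_ex, gm$coding_start_exon)
}

#' Construct a primer pair
#'
#' Both primers are given in genomic coordinates (1-based inclusive). The
#' forward primer anneals on the mRNA-sense strand inside one exon; the
#' reverse primer anneals on the opposite strand inside a downstream exon.
#'
#' @param forward,reverse Length-2 integer vectors `c(start, end)`.
#' @param chrom Chromosome name.
#' @return An object of class `PrimerPair`.
#' @export
PrimerPair <- function(forward, reverse, chrom) {
  stopifnot(length(forward) == 2L, length(reverse) == 2L,
            forward[1L] <= forward[2L], reverse[1L] <= reverse[2L])
  structure(list(chrom = chrom,
                 forward = as.integer(forward),
                 reverse = as.integer(reverse)),
            class = "PrimerPair")
}
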
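#' Simulation configuration
#'
#' @param seed Integer RNG seed; every simulator is a pure function of its
#'   inputs and this seed.
#' @param depth Number of reads to generate.
#' @param read_length Read length in nt (single-end).
#' @param error_rate Per-base substitution probability, in `[0, 0.1]`.
#'   Sequencing error is substitution-only: indels enter reads only through
#'   an [IndelSpectrum], so indel-caller denominators are unambiguous.
#' @return An object of class `SimConfig`.
#' @export
SimConfig <- function(seed = 1L, depth = 1000L, read_length = 75L,
                      error_rate = 0) {
  stopifnot(depth > 0, read_length >= 2L, error_rate >= 0, error_rate <= 0.1)
  structure(list(seed = as.integer(seed), depth = as.integer(depth),
                 read_length = as.integer(read_length),
                 error_rate = error_rate),
            class = "SimConfig")
}

#' Isoform mixture at known PSI
#'
#' Describes the transcript population of one gene as a weighted mixture of
#' isoforms, each an increasing subsequence of the gene's exon labels. The
#' weights are the ground-truth isoform fractions (so for a cassette exon,
#' the inclusion-isoform weight is the true PSI).
#'
#' @param gene A [GeneModel].
#' @param isoforms List of integer vectors of exon labels.
#' @param weights Numeric vector of the same length; must sum to 1.
#' @return An object of class `IsoformMixture`.
#' @export
IsoformMixture <- function(gene, isoforms, weights) {
  stopifnot(length(isoforms) == length(weights),
            all(weights >= 0), abs(sum(weights) - 1) < 1e-9)
  for (iso in isoforms) {
    idx <- match(iso, gene$exons$label)
    if (anyNA(idx) || is.unsorted(idx, strictly = TRUE))
      stop("isoform is not an increasing subsequence of the gene's exons")
  }
  structure(list(gene = gene, isoforms = isoforms, weights = weights),
            class = "IsoformMixture")
}

#' Indel spectrum at a Cas9 cut site
#'
#' The allele table describes the outcome distribution of NHEJ repair at
#' one target site: a reference (unedited) allele plus insertion/deletion
#' alleles with their population fractions.
#'
#' @param chrom Reference (amplicon) name.
#' @param cut 1-based position of the last reference base 5' of the Cas9
#'   scission (blunt cut between `cut` and `cut + 1`; for an SpCas9 guide
#'   this is between protospacer positions 17 and 18, 3 nt 5' of the PAM).
#' @param alleles `data.frame` with columns `type` (`"ref"`, `"ins"`,
#'   `"del"`), `sequence` (inserted bases for `ins`, optional expected
#'   deleted bases for `del`, `""` for `ref`), `length` (indel length) and
#'   `fraction`. Fractions must sum to 1 and a `ref` row must be present.
#' @return An object of class `IndelSpectrum`.
#' @export
IndelSpectrum <- function(chrom, cut, alleles) {
  alleles <- as.data.frame(alleles)
  stopifnot(all(c("type", "fraction") %in% names(alleles)))
  if (is.null(alleles$sequence)) alleles$sequence <- ""
  if (is.null(alleles$length))
    alleles$length <- ifelse(alleles$type == "ref", 0L,
                             nchar(alleles$sequence))
  if (!any(alleles$type == "ref")) stop("spectrum must contain a ref allele")
  if (any(alleles$fraction < 0) || abs(sum(alleles$fraction) - 1) > 1e-9)
    stop("allele fractions must lie in [0,1] and sum to 1")
  structure(list(chrom = chrom, cut = as.integer(cut), alleles = alleles),
            class = "IndelSpectrum")
}

# Internal: run expr with a private, seeded RNG stream.
with_sim_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a genome sequence for a gene model
#'
#' Generates a random chromosome with the gene's exons overwritten by a
#' stop-codon-free coding stream: an ATG at the coding start, sense codons
#' thereafter, and a TAA stop as the last complete codon of the spliced
#' full-length transcript. Intron boundaries receive canonical GT...AG
#' dinucleotides. Optionally plants an additional in-frame ATG codon at a
#' given exon offset (used to probe downstream translation-restart calls).
#'
#' @param gm A [GeneModel].
#' @param seed RNG seed.
#' @param chrom_length Total sequence length (default: last exon end + 200).
#' @param plant_atg Optional `list(exon =, offset =)`: plant an ATG whose
#'   first base is at 1-based `offset` within that exon. The offset must be
#'   in frame with the annotated coding start on the full transcript.
#' @return A single character string (the chromosome sequence).
#' @export
simulate_genome_sequence <- function(gm, seed = 1L, chrom_length = NULL,
                                     plant_atg = NULL) {
  ex <- gm$exons
  if (is.null(chrom_length)) chrom_length <- max(ex$end) + 200L
  stopifnot(chrom_length >= max(ex$end))
  sense_codons <- setdiff(
    apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                      c("A","C","G","T")), 1L, paste0, collapse = ""),
    c("TAA", "TAG", "TGA", "ATG"))
  with_sim_seed(seed, {
    chrom <- sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE)
    len <- sum(ex$end - ex$start + 1L)
    n_cod <- len %/% 3L
    cds <- c("ATG", sample(sense_codons, n_cod - 2L, replace = TRUE), "TAA")
    mrna <- strsplit(paste0(paste(cds, collapse = ""),
                            paste(sample(c("A","C","G","T"), len %% 3L,
                                         replace = TRUE), collapse = "")),
                     "")[[1L]]
    if (!is.null(plant_atg)) {
      idx <- match(plant_atg$exon, ex$label)
      if (is.na(idx)) stop("unknown exon label: ", plant_atg$exon)
      tpos <- sum(ex$end[seq_len(idx - 1L)] - ex$start[seq_len(idx - 1L)] +
                    1L) + plant_atg$offset
      if ((tpos - 1L) %% 3L != 0L)
        stop("planted ATG offset is out of frame on the full transcript")
      mrna[tpos:(tpos + 2L)] <- c("A", "T", "G")
    }
    off <- 0L
    for (i in seq_len(nrow(ex))) {
      w <- ex$end[i] - ex$start[i] + 1L
      chrom[ex$start[i]:ex$end[i]] <- mrna[(off + 1L):(off + w)]
      off <- off + w
    }
    intr <- gene_introns(gm)
    for (i in seq_len(nrow(intr))) {
      if (intr$end[i] - intr$start[i] + 1L >= 4L) {
        chrom[intr$start[i]:(intr$start[i] + 1L)] <- c("G", "T")
        chrom[(intr$end[i] - 1L):intr$end[i]] <- c("A", "G")
      }
    }
    paste(chrom, collapse = "")
  })
}

# Internal: genomic blocks of an mRNA interval [s, e] on an isoform.
# exons: data.frame rows of the isoform's exons in order.
mrna_to_blocks <- function(exons, s, e) {
  widths <- exons$end - exons$start + 1L
  bounds <- cumsum(widths)               # mRNA position of each exon's last nt
  first <- c(1L, utils::head(bounds, -1L) + 1L)
  keep <- which(bounds >= s & first <= e)
  gs <- exons$start[keep] + pmax(s - first[keep], 0L)
  ge <- exons$start[keep] + pmin(e - first[keep], widths[keep] - 1L)
  data.frame(start = gs, end = ge)
}

# Internal: CIGAR string from genomic blocks (M/N ops).
blocks_to_cigar <- function(blocks) {
  m <- blocks$end - blocks$start + 1L
  if (nrow(blocks) == 1L) return(paste0(m, "M"))
  n <- blocks$start[-1L] - blocks$end[-nrow(blocks)] - 1L
  paste0(paste0(m[-length(m)], "M", n, "N", collapse = ""),
         m[length(m)], "M")
}

#' Simulate junction-spanning RNA-seq reads at a known isoform mixture
#'
#' Each read is drawn by (1) choosing an isoform by weight, (2) choosing a
#' start uniformly over valid mRNA positions, and (3) emitting a spliced
#' alignment whose gapped segments (M/N CIGAR) match the genomic exon
#' blocks. No fragment-length model and no pairing: junction counting is
#' the only downstream consumer.
#'
#' The truth table records the isoform of every read, plus per-junction
#' counts computed arithmetically from the (isoform, start) placements --
#' both the exact number of simulated reads spanning each junction with at
#' least `min_overhang` nt on both sides, and its binomial expectation from
#' placement geometry. This is the oracle against which the CIGAR-based
#' junction counter is tested.
#'
#' @param mix An [IsoformMixture].
#' @param cfg A [SimConfig].
#' @param min_overhang Overhang (nt) used for the truth-table counts.
#' @param genome Optional chromosome sequence; when supplied, reads carry
#'   real bases (with substitution errors at `cfg$error_rate`), otherwise
#'   `seq`/`qual` are `"*"`.
#' @param duplicate_fraction Fraction of extra duplicate reads (identical
#'   placement) appended to the output; default 0. Only used to exercise
#'   deduplication.
#' @return List with `alignments` (data.frame of SAM fields), `truth`
#'   (list: `reads`, `junctions`), and `seqlengths`.
#' @export
simulate_junction_reads <- function(mix, cfg, min_overhang = 6L,
                                    genome = NULL, duplicate_fraction = 0) {
  gm <- mix$gene
  iso_ex <- lapply(mix$isoforms, function(lab)
    gm$exons[match(lab, gm$exons$label), , drop = FALSE])
  iso_len <- vapply(iso_ex, function(e) sum(e$end - e$start + 1L), integer(1))
  rl <- cfg$read_length
  if (any(iso_len < rl)) stop("read too long for isoform mRNA")
  for (e in iso_ex) if (nrow(e) < 2L)
    stop("every isoform must have at least 2 exons")

  with_sim_seed(cfg$seed, {
    k <- sample.int(length(mix$isoforms), cfg$depth, replace = TRUE,
                    prob = mix$weights)
    s <- vapply(k, function(ki) sample.int(iso_len[ki] - rl + 1L, 1L),
                integer(1))
    # placements repeat heavily at depth >> mRNA length: compute each
    # distinct (isoform, start) once
    pkey <- paste0(k, ":", s)
    uniq <- !duplicated(pkey)
    urec <- lapply(which(uniq), function(i) {
      b <- mrna_to_blocks(iso_ex[[k[i]]], s[i], s[i] + rl - 1L)
      list(pos = b$start[1L], cigar = blocks_to_cigar(b), blocks = b)
    })
    recs <- urec[match(pkey, pkey[uniq])]
    seqs <- if (is.null(genome)) rep("*", cfg$depth) else {
      vapply(recs, function(r) {
        bases <- unlist(lapply(seq_len(nrow(r$blocks)), function(j)
          strsplit(substr(genome, r$blocks$start[j], r$blocks$end[j]),
                   "")[[1L]]))
        if (cfg$error_rate > 0) {
          hit <- stats::runif(length(bases)) < cfg$error_rate
          bases[hit] <- vapply(bases[hit], function(bb)
            sample(setdiff(c("A","C","G","T"), bb), 1L), character(1))
        }
        paste(bases, collapse = "")
      }, character(1))
    }
    aln <- data.frame(
      qname = sprintf("read%06d", seq_len(cfg$depth)),
      flag = 0L, rname = gm$chrom,
      pos = vapply(recs, `[[`, integer(1), "pos"),
      mapq = 60L,
      cigar = vapply(recs, `[[`, character(1), "cigar"),
      seq = seqs,
      qual = ifelse(seqs == "*", "*",
                    strrep("I", rl)),
      stringsAsFactors = FALSE)
    if (duplicate_fraction > 0) {
      ndup <- ceiling(duplicate_fraction * cfg$depth)
      pick <- sample.int(cfg$depth, ndup, replace = TRUE)
      dup <- aln[pick, , drop = FALSE]
      dup$qname <- sprintf("dup%06d", seq_len(ndup))
      aln <- rbind(aln, dup)
      k <- c(k, k[pick]); s <- c(s, s[pick])
    }

    # truth: junction spans computed from placement arithmetic, not CIGARs
    jx <- unique(do.call(rbind, lapply(mix$isoforms, function(lab)
      data.frame(donor = lab[-length(lab)], acceptor = lab[-1L]))))
    jx <- jx[order(jx$donor, jx$acceptor), , drop = FALSE]
    observed <- expected <- numeric(nrow(jx))
    for (j in seq_len(nrow(jx))) {
      obs <- 0L; exp_j <- 0
      for (ki in seq_along(mix$isoforms)) {
        lab <- mix$isoforms[[ki]]
        t <- which(lab[-length(lab)] == jx$donor[j] &
                     lab[-1L] == jx$acceptor[j])
        if (length(t) == 0L) next
        bt <- cumsum(iso_ex[[ki]]$end - iso_ex[[ki]]$start + 1L)[t]
        lo <- max(1L, bt + min_overhang - rl + 1L)
        hi <- min(bt - min_overhang + 1L, iso_len[ki] - rl + 1L)
        in_span <- k == ki & s >= lo & s <= hi
        obs <- obs + sum(in_span)
        n_valid <- max(0L, hi - lo + 1L)
        exp_j <- exp_j + cfg$depth * mix$weights[ki] *
          n_valid / (iso_len[ki] - rl + 1L)
      }
      observed[j] <- obs; expected[j] <- exp_j
    }
    list(alignments = aln,
         truth = list(
           reads = data.frame(qname = aln$qname, isoform = k),
           junctions = cbind(jx, data.frame(observed = observed,
                                            expected = expected))),
         seqlengths = stats::setNames(max(gm$exons$end) + 500L, gm$chrom))
  })
}

#' Simulate amplicon deep-sequencing reads over an edited target site
#'
#' Every read covers the whole amplicon and carries exactly one allele
#' drawn from the spectrum, plus substitution errors at the configured
#' rate. Insertions are placed between `cut` and `cut + 1`; deletions
#' remove `length` bases starting at `cut + 1`. Alignments are emitted
#' directly (M/I/D CIGARs), mirroring how an aligner would place each
#' allele at the cut site before any left-normalisation.
#'
#' @param spectrum An [IndelSpectrum].
#' @param ref_sequence Amplicon reference sequence (character scalar).
#' @param cfg A [SimConfig] (`read_length` is ignored: reads span the
#'   amplicon).
#' @return List with `reads` (character vector), `alignments` (data.frame
#'   of SAM fields), `truth` (per-allele counts), and `seqlengths`.
#' @export
simulate_amplicon_reads <- function(spectrum, ref_sequence, cfg) {
  n <- nchar(ref_sequence)
  cut <- spectrum$cut
  if (cut < 20L || n - cut < 20L) stop("insufficient flank around cut site")
  al <- spectrum$alleles
  # allele sequences and cigars
  mk <- function(i) {
    type <- al$type[i]
    if (type == "ref") {
      list(seq = ref_sequence, cigar = paste0(n, "M"))
    } else if (type == "ins") {
      ins <- al$sequence[i]
      stopifnot(nchar(ins) >= 1L)
      list(seq = paste0(substr(ref_sequence, 1L, cut), ins,
                        substr(ref_sequence, cut + 1L, n)),
           cigar = paste0(cut, "M", nchar(ins), "I", n - cut, "M"))
    } else if (type == "del") {
      L <- as.integer(al$length[i])
      stopifnot(L >= 1L, cut + L <= n)
      removed <- substr(ref_sequence, cut + 1L, cut + L)
      if (nzchar(al$sequence[i]) && al$sequence[i] != removed)
        stop("deleted sequence does not match reference at the cut site")
      list(seq = paste0(substr(ref_sequence, 1L, cut),
                        substr(ref_sequence, cut + L + 1L, n)),
           cigar = paste0(cut, "M", L, "D", n - cut - L, "M"))
    } else stop("unknown allele type: ", type)
  }
  templates <- lapply(seq_len(nrow(al)), mk)
  with_sim_seed(cfg$seed, {
    a <- sample.int(nrow(al), cfg$depth, replace = TRUE, prob = al$fraction)
    reads <- vapply(a, function(ai) {
      seq <- templates[[ai]]$seq
      if (cfg$error_rate > 0) {
        bases <- strsplit(seq, "")[[1L]]
        hit <- stats::runif(length(bases)) < cfg$error_rate
        bases[hit] <- vapply(bases[hit], function(bb)
          sample(setdiff(c("A","C","G","T"), bb), 1L), character(1))
        seq <- paste(bases, collapse = "")
      }
      seq
    }, character(1))
    aln <- data.frame(
      qname = sprintf("amp%06d", seq_len(cfg$depth)),
      flag = 0L, rname = spectrum$chrom, pos = 1L, mapq = 60L,
      cigar = vapply(a, function(ai) templates[[ai]]$cigar, character(1)),
      seq = reads, qual = vapply(reads, function(x) strrep("I", nchar(x)),
                                 character(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
    truth <- cbind(al, count = tabulate(a, nbins = nrow(al)))
    list(reads = stats::setNames(reads, aln$qname), alignments = aln,
         truth = truth,
         seqlengths = stats::setNames(n, spectrum$chrom))
  })
}

#' Apply a genomic deletion to a chromosome sequence
#'
#' Removes the closed interval `[start, end]` and returns the mutated
#' sequence together with a truth record of the lesion: removed length,
#' the coordinate shift for all downstream positions, and the exons of the
#' gene model that fall fully inside the deleted interval.
#'
#' @param gene A [GeneModel] on the same chromosome.
#' @param genome_sequence Chromosome sequence (character scalar).
#' @param breakpoints Length-2 vector `c(start, end)`, 1-based inclusive.
#' @return List with `sequence` (mutated) and `truth`
#'   (`removed_length`, `shift`, `start`, `end`, `removed_exons`).
#' @export
apply_deletion <- function(gene, genome_sequence, breakpoints) {
  s <- as.integer(breakpoints[1L]); e <- as.integer(breakpoints[2L])
  n <- nchar(genome_sequence)
  if (s < 1L || e > n || s > e) stop("breakpoints out of range")
  removed <- e - s + 1L
  ex <- gene$exons
  gone <- ex$label[ex$start >= s & ex$end <= e]
  list(sequence = paste0(substr(genome_sequence, 1L, s - 1L),
                         substr(genome_sequence, e + 1L, n)),
       truth = list(removed_length = removed, shift = -removed,
                    start = s, end = e, removed_exons = gone))
}

#' Simulate gene-level RNA-seq counts for a clone-vs-parent comparison
#'
#' Parental replicates are drawn around `base_mean` and clone replicates
#' around `base_mean * (1 - reduction)`, with negative-binomial noise at a
#' fixed dispersion (variance = mu + dispersion * mu^2). The generating
#' reduction is returned as truth for estimator-recovery tests.
#'
#' @param base_mean Mean normalised count in the parental line.
#' @param reduction Fractional reduction in the clone, in `[0, 1)`.
#' @param n_replicates Replicates per group.
#' @param seed RNG seed.
#' @param dispersion NB dispersion (default 0.005, typical of a
#'   deeply-sequenced, highly expressed gene).
#' @return List with `counts` (data.frame: `sample`, `group`, `count`) and
#'   `truth` (`reduction`).
#' @export
simulate_gene_counts <- function(base_mean, reduction, n_replicates = 3L,
                                 seed = 1L, dispersion = 0.005) {
  stopifnot(reduction >= 0, reduction < 1, base_mean > 0, n_replicates >= 1)
  with_sim_seed(seed, {
    parent <- stats::rnbinom(n_replicates, mu = base_mean,
                             size = 1 / dispersion)
    clone <- stats::rnbinom(n_replicates, mu = base_mean * (1 - reduction),
                            size = 1 / dispersion)
    list(counts = data.frame(
           sample = c(sprintf("parent_%d", seq_len(n_replicates)),
                      sprintf("clone_%d", seq_len(n_replicates))),
           group = rep(c("parent", "clone"), each = n_replicates),
           count = c(parent, clone)),
         truth = list(reduction = reduction))
  })
}
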
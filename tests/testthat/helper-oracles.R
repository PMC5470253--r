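# Shared helpers: hand-built containers and independent brute-force oracles.

# JunctionCounts from a named count vector, e.g. c("1-2" = 64, ...).
make_counts <- function(counts, sample_id = "s", n_total = sum(counts)) {
  structure(list(sample_id = sample_id, counts = counts,
                 n_total_gene_reads = as.integer(n_total)),
            class = "JunctionCounts")
}

# Brute-force junction-span oracle: for one isoform (exon rows in order)
# and read start s, list the junctions (donor, acceptor labels) the read
# spans with >= h nt on both sides, by per-base enumeration of the
# mRNA-to-genome map. Independent of both the simulator's interval
# arithmetic and the CIGAR-based counter.
brute_junctions <- function(exon_rows, s, read_length, h) {
  gpos <- unlist(lapply(seq_len(nrow(exon_rows)), function(i)
    exon_rows$start[i]:exon_rows$end[i]))
  lab <- rep(exon_rows$label, exon_rows$end - exon_rows$start + 1L)
  idx <- s:(s + read_length - 1L)
  rl_lab <- lab[idx]
  out <- list()
  for (t in seq_len(read_length - 1L)) {
    if (rl_lab[t] != rl_lab[t + 1L]) {
      left <- sum(rl_lab[seq_len(t)] == rl_lab[t])
      right <- sum(rl_lab[(t + 1L):read_length] == rl_lab[t + 1L])
      if (left >= h && right >= h)
        out[[length(out) + 1L]] <- c(rl_lab[t], rl_lab[t + 1L])
    }
  }
  out
}

# Expected junction counts by full placement enumeration (brute force).
brute_expected_counts <- function(mix, depth, read_length, h) {
  acc <- new.env(parent = emptyenv())
  for (k in seq_along(mix$isoforms)) {
    ex <- mix$gene$exons[match(mix$isoforms[[k]], mix$gene$exons$label), ]
    L <- sum(ex$end - ex$start + 1L)
    n_starts <- L - read_length + 1L
    for (s in seq_len(n_starts)) {
      for (j in brute_junctions(ex, s, read_length, h)) {
        key <- paste0(j[1L], "-", j[2L])
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) +
          depth * mix$weights[k] / n_starts
      }
    }
  }
  keys <- ls(acc)
  stats::setNames(vapply(keys, function(kk) acc[[kk]], numeric(1)), keys)
}

# Independent translation helper for the frame oracle: peptide of an
# isoform's transcript read from the annotated start, up to the first stop.
peptide_of <- function(gm, genome, isoform) {
  mrna <- transcript_sequence(gm, genome, isoform)
  n_cod <- nchar(mrna) %/% 3L
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(mrna, 1L, 3L * n_cod)),
    if.fuzzy.codon = "solve"))
  sub("\\*.*$", "", aa)
}
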
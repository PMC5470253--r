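test_that("frame phase follows the mod-3 rule on fixture cassettes", {
  dmd <- build_fixture("dmd")$model
  fr <- frame_report(dmd, 23)
  expect_equal(fr$skipped_length, 213L)
  expect_true(fr$in_frame)

  cb <- build_fixture("ctnnb1")$model
  expect_true(frame_report(cb, 3)$in_frame)            # 228 nt
  fr34 <- frame_report(cb, 3:4)                        # 412 nt
  expect_equal(fr34$skipped_length, 412L)
  expect_false(fr34$in_frame)

  kras <- build_fixture("kras")$model
  expect_false(frame_report(kras, 2)$in_frame)         # 122 nt

  expect_error(frame_report(kras, 1), "not a cassette skip")
  expect_error(frame_report(kras, 3), "not a cassette skip")
})

test_that("a planted in-frame downstream ATG is reported after a frameshift", {
  kras <- build_fixture("kras")$model
  # exon 3 starts at transcript position 323 (200 + 122 + 1); choose an
  # in-frame offset within exon 3: transcript pos 400 -> offset 78
  genome <- simulate_genome_sequence(kras, seed = 41,
                                     plant_atg = list(exon = 3, offset = 78))
  fr <- frame_report(kras, 2, genome = genome)
  expect_false(fr$in_frame)
  expect_false(is.null(fr$downstream_start))
  expect_equal(fr$downstream_start$exon, 3L)
  # reported ATG is in the annotated frame and at/before the planted one
  expect_equal((fr$downstream_start$transcript_pos - 1L) %% 3L, 0L)
  expect_lte(fr$downstream_start$transcript_pos, 400L)
  # and it is a real ATG on the transcript
  mrna <- transcript_sequence(kras, genome)
  expect_equal(substr(mrna, fr$downstream_start$transcript_pos,
                      fr$downstream_start$transcript_pos + 2L), "ATG")
})

test_that("frame calls agree with brute-force translation of transcripts", {
  cb <- build_fixture("ctnnb1")$model
  for (seed in 1:5) {
    genome <- simulate_genome_sequence(cb, seed = seed)
    full <- peptide_of(cb, genome, cb$exons$label)
    for (skip in list(3L, 3:4, 4L, 5L, 4:5)) {
      fr <- frame_report(cb, skip)
      pep <- peptide_of(cb, genome, setdiff(cb$exons$label, skip))
      # in-frame skip: downstream frame preserved, so either the full
      # C-terminus is intact or translation stops exactly at the new
      # junction codon (an in-frame junction can by chance form a stop);
      # frameshift: the downstream peptide always diverges
      tail_full <- substr(full, nchar(full) - 9L, nchar(full))
      same_tail <- nchar(pep) > 10L &&
        substr(pep, nchar(pep) - 9L, nchar(pep)) == tail_full
      lens <- exon_lengths(cb)
      pre <- sum(lens[as.character(
        cb$exons$label[cb$exons$label < min(skip)])])
      if (fr$in_frame) {
        expect_true(same_tail || nchar(pep) == pre %/% 3L,
                    info = paste("seed", seed, "skip",
                                 paste(skip, collapse = "+")))
      } else {
        expect_false(same_tail,
                     info = paste("seed", seed, "skip",
                                  paste(skip, collapse = "+")))
      }
    }
  }
})

test_that("RT-PCR product sizes match the published band sizes", {
  kras <- build_fixture("kras")
  expect_equal(predict_amplicon_size(kras$model, c(1, 2, 3), kras$primers),
               331L)
  expect_equal(predict_amplicon_size(kras$model, c(1, 3), kras$primers),
               209L)
  dmd <- build_fixture("dmd")
  expect_equal(predict_amplicon_size(dmd$model, c(22, 23, 24), dmd$primers),
               353L)
  expect_equal(predict_amplicon_size(dmd$model, c(22, 24), dmd$primers),
               140L)
  # primer exon absent from the isoform: no product
  expect_true(is.na(predict_amplicon_size(kras$model, c(2, 3), kras$primers)))
  # primer spanning an exon boundary is rejected
  bad <- PrimerPair(forward = c(195, 216), reverse = c(1124, 1146),
                    chrom = "chrK")
  expect_error(predict_amplicon_size(kras$model, c(1, 2, 3), bad),
               "unsupported primer placement")
})

test_that("band-size difference equals the skipped length whenever primers flank", {
  set.seed(7)
  for (rep in 1:20) {
    n_ex <- sample(3:6, 1)
    lens <- sample(60:300, n_ex, replace = TRUE)
    gaps <- sample(100:400, n_ex - 1, replace = TRUE)
    starts <- cumsum(c(1, lens[-n_ex] + gaps))
    gm <- GeneModel("rand", "chrR", "+",
                    data.frame(label = seq_len(n_ex), start = starts,
                               end = starts + lens - 1))
    pr <- PrimerPair(
      forward = c(starts[1], starts[1] + 19),
      reverse = c(starts[n_ex] + lens[n_ex] - 20,
                  starts[n_ex] + lens[n_ex] - 1),
      chrom = "chrR")
    cassette <- if (n_ex == 3L) 2L else sample(2:(n_ex - 1), 1)
    full <- predict_amplicon_size(gm, seq_len(n_ex), pr)
    skip <- predict_amplicon_size(gm, setdiff(seq_len(n_ex), cassette), pr)
    expect_equal(full - skip, unname(exon_lengths(gm)[cassette]))
  }
})

test_that("large deletions are interpreted against the gene model", {
  p65 <- build_fixture("p65")
  da <- interpret_deletion(p65$model, 400, 2667)
  expect_equal(da$length, 2268L)
  expect_equal(da$removed_exons, c(5L, 6L, 7L))
  expect_equal(da$context_5p$kind, "intronic")
  expect_equal(da$context_3p$kind, "intronic")
  expect_equal(da$predicted_junction, c(4L, 8L))

  cb <- build_fixture("ctnnb1")
  dc <- interpret_deletion(cb$model, 160, 991)
  expect_equal(dc$length, 832L)
  expect_equal(dc$context_5p, list(kind = "intronic", unit = 2L))
  expect_equal(dc$context_3p, list(kind = "exonic", unit = 4L))
  expect_equal(dc$removed_exons, 3L)
  expect_match(dc$predicted_transcript, "intron 2")
  expect_match(dc$predicted_transcript, "exon 4")

  # wholly intronic deletion: transcript unchanged
  di <- interpret_deletion(p65$model, 200, 300)
  expect_equal(length(di$removed_exons), 0L)
  expect_match(di$predicted_transcript, "unchanged")

  expect_error(interpret_deletion(p65$model, 5000, 6000),
               "deletion outside gene")
})

test_that("deletion length and removed exons behave under interval growth", {
  p65 <- build_fixture("p65")$model
  prev <- -1L
  for (end in seq(500, 3100, by = 250)) {
    da <- interpret_deletion(p65, 400, end)
    expect_equal(da$length, end - 400L + 1L)
    expect_gte(length(da$removed_exons), prev)
    prev <- length(da$removed_exons)
  }
})
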
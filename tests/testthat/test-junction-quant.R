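kras <- build_fixture("kras")$model

one_read <- function(pos, cigar, qname = "r1") {
  data.frame(qname = qname, flag = 0L, rname = "chrK", pos = pos,
             mapq = 60L, cigar = cigar, seq = "*", qual = "*",
             stringsAsFactors = FALSE)
}

test_that("a junction read is assigned by exon-boundary abutment", {
  # 30M ends at exon1 end (200), resumes at exon2 start (501), 45M
  jc <- count_junction_reads(one_read(171L, "30M300N45M"), kras)
  expect_equal(unname(jc$counts["1-2"]), 1L)
  expect_equal(length(jc$counts), 1L)
})

test_that("reads with short overhang are counted nowhere", {
  jc <- count_junction_reads(one_read(171L, "30M300N3M"), kras,
                             min_overhang = 6)
  expect_equal(length(jc$counts), 0L)
  expect_equal(jc$n_total_gene_reads, 1L)
  # overhang exactly at the threshold counts
  jc6 <- count_junction_reads(one_read(195L, "6M300N6M"), kras,
                              min_overhang = 6)
  expect_equal(unname(jc6$counts["1-2"]), 1L)
})

test_that("junctions off annotated boundaries are reported as novel", {
  jc <- count_junction_reads(one_read(161L, "30M310N45M"), kras)
  expect_match(names(jc$counts), "^novel:")
  expect_equal(unname(jc$counts[1]), 1L)
})

test_that("counter reproduces simulator truth exactly across seeds", {
  for (seed in 1:10) {
    mix <- IsoformMixture(kras, list(1:3, c(1, 3)), c(0.6, 0.4))
    sim <- simulate_junction_reads(mix, SimConfig(seed = seed, depth = 400))
    jc <- count_junction_reads(sim$alignments, kras)
    tt <- sim$truth$junctions
    for (i in seq_len(nrow(tt))) {
      key <- paste0(tt$donor[i], "-", tt$acceptor[i])
      got <- if (key %in% names(jc$counts)) unname(jc$counts[key]) else 0L
      expect_equal(got, tt$observed[i], info = paste("seed", seed, key))
    }
  }
})

test_that("counting is invariant to read order and to duplicates under dedup", {
  mix <- IsoformMixture(kras, list(1:3, c(1, 3)), c(0.5, 0.5))
  sim <- simulate_junction_reads(mix, SimConfig(seed = 3, depth = 300))
  base <- count_junction_reads(sim$alignments, kras)
  shuf <- sim$alignments[sample.int(nrow(sim$alignments)), ]
  expect_equal(count_junction_reads(shuf, kras)$counts[names(base$counts)],
               base$counts)

  dup <- simulate_junction_reads(mix, SimConfig(seed = 3, depth = 300),
                                 duplicate_fraction = 0.4)
  with_dup <- count_junction_reads(dup$alignments, kras, dedup = TRUE)
  # dedup collapses identical placements, including original coincidences
  no_dup <- count_junction_reads(sim$alignments, kras, dedup = TRUE)
  expect_equal(with_dup$counts[names(no_dup$counts)], no_dup$counts)
})

test_that("unmapped/empty input warns and returns empty counts", {
  empty <- data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(), mapq = integer(),
                      cigar = character(), seq = character(),
                      qual = character())
  sam <- tempfile(fileext = ".sam")
  write_sam(empty, sam, c(chrK = 2000L))
  expect_warning(jc <- count_junction_reads(sam, kras), "no mapped reads")
  expect_equal(jc$n_total_gene_reads, 0L)
})

test_that("PSI follows the junction-count formula", {
  expect_equal(compute_psi(make_counts(c("1-2" = 50, "2-3" = 50, "1-3" = 0)),
                           c(1, 2, 3)), 1.0)
  expect_equal(compute_psi(make_counts(c("1-2" = 0, "2-3" = 0, "1-3" = 30)),
                           c(1, 2, 3)), 0.0)
  expect_equal(compute_psi(make_counts(c("1-2" = 64, "2-3" = 64, "1-3" = 72)),
                           c(1, 2, 3)), 0.64)
  expect_warning(
    p <- compute_psi(make_counts(c("4-5" = 10)), c(1, 2, 3)),
    "no informative reads")
  expect_true(is.na(p))
})

test_that("donor-usage fractions normalise junctions leaving the donor", {
  expect_equal(donor_usage_fractions(
    make_counts(c("2-3" = 80, "2-4" = 20)), 2),
    c("3" = 0.8, "4" = 0.2))
  expect_equal(donor_usage_fractions(
    make_counts(c("2-3" = 0, "2-4" = 10, "2-5" = 10)), 2),
    c("3" = 0, "4" = 0.5, "5" = 0.5))
  expect_error(donor_usage_fractions(make_counts(c("3-4" = 5)), 2),
               "no informative reads")
})

test_that("promiscuous-skipping ladder fractions recover mixture weights", {
  cb <- build_fixture("ctnnb1")$model
  w <- c(0.55, 0.25, 0.12, 0.08)
  mix <- IsoformMixture(cb, list(2:7, c(2, 4:7), c(2, 5:7), c(2, 6:7)), w)
  sim <- simulate_junction_reads(mix, SimConfig(seed = 17, depth = 8000))
  jc <- count_junction_reads(sim$alignments, cb)
  fr <- donor_usage_fractions(jc, 2)
  # each acceptor fraction within 3 s.d. of its expected share
  tt <- sim$truth$junctions
  from2 <- tt[tt$donor == 2, ]
  exp_fr <- from2$expected / sum(from2$expected)
  n <- sum(from2$observed)
  for (i in seq_len(nrow(from2))) {
    sd3 <- 3 * sqrt(exp_fr[i] * (1 - exp_fr[i]) / n)
    expect_lt(abs(fr[as.character(from2$acceptor[i])] - exp_fr[i]), sd3)
  }
})

test_that("expression change is the percent drop in mean counts", {
  expect_equal(expression_change(c(100, 100), c(100, 100)), 0)
  expect_equal(expression_change(81, 100), 19)
  expect_equal(expression_change(120, 100), -20)  # increase allowed
  expect_error(expression_change(10, 0), "undefined reduction")
})

test_that("inclusion-weight estimator inverts the statistic's geometry", {
  # inclusion_weight_for_psi is the exact inverse of the estimator's
  # expectation: round-trip through simulated data at depth 1e4
  w <- inclusion_weight_for_psi(kras, c(1, 2, 3), psi = 0.64,
                                read_length = 75)
  mix <- IsoformMixture(kras, list(1:3, c(1, 3)), c(w, 1 - w))
  sim <- simulate_junction_reads(mix, SimConfig(seed = 19, depth = 10000))
  jc <- count_junction_reads(sim$alignments, kras)
  expect_equal(compute_psi(jc, c(1, 2, 3)), 0.64, tolerance = 0.03)
  expect_equal(estimate_inclusion_weight(jc, kras, c(1, 2, 3), 75), w,
               tolerance = 0.03)
})
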
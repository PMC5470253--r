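kras <- build_fixture("kras")$model

test_that("junction-read simulator is a pure function of inputs and seed", {
  mix <- IsoformMixture(kras, list(1:3, c(1, 3)), c(0.5, 0.5))
  cfg <- SimConfig(seed = 42, depth = 500)
  a <- simulate_junction_reads(mix, cfg)
  b <- simulate_junction_reads(mix, cfg)
  expect_identical(a, b)
  # byte-identical SAM output
  fa <- tempfile(fileext = ".sam"); fb <- tempfile(fileext = ".sam")
  write_sam(a$alignments, fa, a$seqlengths)
  write_sam(b$alignments, fb, b$seqlengths)
  expect_identical(readLines(fa), readLines(fb))
  c <- simulate_junction_reads(mix, SimConfig(seed = 43, depth = 500))
  expect_false(identical(a$alignments, c$alignments))
})

test_that("pure inclusion mixture yields no exclusion-junction truth", {
  mix <- IsoformMixture(kras, list(1:3), 1)
  sim <- simulate_junction_reads(mix, SimConfig(seed = 1, depth = 1000))
  tt <- sim$truth$junctions
  excl <- tt[tt$donor == 1 & tt$acceptor == 3, ]
  expect_true(nrow(excl) == 0 ||
                (excl$observed == 0 && excl$expected == 0))
})

test_that("exclusion-read fraction follows the placement binomial", {
  mix <- IsoformMixture(kras, list(1:3, c(1, 3)), c(0.5, 0.5))
  cfg <- SimConfig(seed = 11, depth = 10000)
  sim <- simulate_junction_reads(mix, cfg)
  tt <- sim$truth$junctions
  row <- tt[tt$donor == 1 & tt$acceptor == 3, ]
  p <- row$expected / cfg$depth
  sd3 <- 3 * sqrt(cfg$depth * p * (1 - p))
  expect_lt(abs(row$observed - row$expected), sd3)
})

test_that("simulator truth agrees with brute-force placement enumeration", {
  gm <- GeneModel("toy", "chrT", "+",
                  data.frame(label = 1:3, start = c(1, 61, 161),
                             end = c(40, 120, 220)))
  mix <- IsoformMixture(gm, list(1:3, c(1, 3)), c(0.7, 0.3))
  cfg <- SimConfig(seed = 5, depth = 2000, read_length = 20)
  sim <- simulate_junction_reads(mix, cfg, min_overhang = 4)
  tt <- sim$truth$junctions
  brute <- brute_expected_counts(mix, cfg$depth, cfg$read_length, h = 4)
  for (i in seq_len(nrow(tt))) {
    key <- paste0(tt$donor[i], "-", tt$acceptor[i])
    expect_equal(tt$expected[i], unname(brute[key]), tolerance = 1e-12,
                 info = key)
  }
})

test_that("overlong reads are rejected", {
  mix <- IsoformMixture(kras, list(c(1, 3)), 1)  # mRNA 600 nt
  expect_error(
    simulate_junction_reads(mix, SimConfig(seed = 1, depth = 10,
                                           read_length = 601)),
    "read too long")
})

test_that("amplicon simulator reproduces its spectrum", {
  ref <- simulate_genome_sequence(
    GeneModel("amp", "amp", "+", data.frame(label = 1, start = 1, end = 200)),
    seed = 3, chrom_length = 200)

  # pure reference: no indels anywhere
  spec0 <- IndelSpectrum("amp", 100, data.frame(
    type = "ref", sequence = "", length = 0, fraction = 1))
  sim0 <- simulate_amplicon_reads(spec0, ref, SimConfig(seed = 2, depth = 200))
  expect_true(all(sim0$reads == ref))

  # +T at 65%: allele draw within 3 binomial s.d. of truth
  spec <- IndelSpectrum("amp", 100, data.frame(
    type = c("ins", "ref"), sequence = c("T", ""), length = c(1, 0),
    fraction = c(0.65, 0.35)))
  sim <- simulate_amplicon_reads(spec, ref, SimConfig(seed = 7, depth = 5000))
  n_ins <- sim$truth$count[sim$truth$type == "ins"]
  expect_lt(abs(n_ins - 5000 * 0.65), 3 * sqrt(5000 * 0.65 * 0.35))
  expect_equal(sum(sim$truth$count), 5000)

  # deterministic deletion allele with zero error rate
  del2 <- substr(ref, 101, 102)
  spec_del <- IndelSpectrum("amp", 100, data.frame(
    type = c("del", "ref"), sequence = c(del2, ""), length = c(2, 0),
    fraction = c(1 - 1e-12, 1e-12)))
  sim_del <- simulate_amplicon_reads(spec_del, ref,
                                     SimConfig(seed = 1, depth = 100))
  expected <- paste0(substr(ref, 1, 100), substr(ref, 103, 200))
  expect_true(all(sim_del$reads == expected))

  # cut too close to an end
  spec_edge <- IndelSpectrum("amp", 10, data.frame(
    type = "ref", sequence = "", length = 0, fraction = 1))
  expect_error(simulate_amplicon_reads(spec_edge, ref, SimConfig(seed = 1)),
               "insufficient flank")
})

test_that("apply_deletion removes the closed interval and records truth", {
  seq <- "ACGTACGTAC"
  one <- apply_deletion(kras, seq, c(5, 5))
  expect_equal(one$sequence, "ACGTCGTAC")
  expect_equal(one$truth$removed_length, 1L)
  expect_equal(one$truth$shift, -1L)
  expect_error(apply_deletion(kras, seq, c(5, 11)), "out of range")

  p65 <- build_fixture("p65")
  g <- simulate_genome_sequence(p65$model, seed = 9)
  bp <- p65$editing$deletion_2268
  del <- apply_deletion(p65$model, g, bp)
  expect_equal(del$truth$removed_length, 2268L)
  expect_equal(del$truth$removed_exons, c(5L, 6L, 7L))
  expect_equal(nchar(del$sequence), nchar(g) - 2268L)

  cb <- build_fixture("ctnnb1")
  gc <- simulate_genome_sequence(cb$model, seed = 9)
  delc <- apply_deletion(cb$model, gc, cb$editing$deletion_832)
  expect_equal(delc$truth$removed_length, 832L)
  expect_equal(delc$truth$removed_exons, 3L)
})

test_that("gene-count simulator recovers the generating reduction", {
  # no reduction: clone/parent means agree within noise at large n
  null <- simulate_gene_counts(5e4, 0, n_replicates = 50, seed = 21)
  est0 <- expression_change(
    null$counts$count[null$counts$group == "clone"],
    null$counts$count[null$counts$group == "parent"])
  expect_lt(abs(est0), 5)

  # bias check: average the estimator over repeated small experiments
  recover <- function(r, n_rep, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_gene_counts(5e4, r, n_replicates = n_rep, seed = s)
      expression_change(sim$counts$count[sim$counts$group == "clone"],
                        sim$counts$count[sim$counts$group == "parent"])
    }, numeric(1)))
  }
  expect_equal(recover(0.19, 3, 1:100), 19, tolerance = 0.1)
  expect_equal(recover(0.47, 2, 1:100), 47, tolerance = 0.1)
})
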
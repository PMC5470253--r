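#' Packaged toy gene models
#'
#' Four toy loci on synthetic chromosomes mirror the structure of the genes
#' in which CRISPR-induced exon skipping is studied: mouse Kras (cassette
#' exon 2 between exons 1 and 3), Ctnnb1 (in-frame exon 3 plus downstream
#' exons 4--7), Dmd (in-frame cassette exon 23) and p65/RelA (exons 4--8).
#' Coordinates are synthetic but constrained by the experimentally printed
#' quantities: exon lengths reproduce the published RT-PCR band-size
#' differences (Kras exon 2 = 331 - 209 = 122 nt; Dmd exon 23 =
#' 353 - 140 = 213 nt), Ctnnb1 exon 3 is 228 nt (divisible by 3, an
#' in-frame cassette) with downstream exon lengths chosen so that only the
#' exon 2-4 splice product stays in frame, and the p65 intron structure
#' admits a 2268-bp deletion removing exons 5--7. Flank splits within the
#' primers are free choices; only their sums are constrained.
#'
#' @param name One of `"kras"`, `"ctnnb1"`, `"dmd"`, `"p65"`.
#' @return A list with components `model` (a [GeneModel]), `primers`
#'   (a [PrimerPair] or `NULL`) and `editing` (a list of editing metadata:
#'   sgRNA cut sites, known deletion breakpoints, or `NULL`).
#' @examples
#' fx <- build_fixture("kras")
#' exon_lengths(fx$model)
#' @export
build_fixture <- function(name = c("kras", "ctnnb1", "dmd", "p65")) {
  if (length(name) > 1L) name <- name[1L]
  if (!name %in% c("kras", "ctnnb1", "dmd", "p65"))
    stop("no such fixture: ", name)
  switch(name,
    kras = list(
      model = GeneModel("Kras", "chrK", "+",
        data.frame(label = 1:3,
                   start = c(1L, 501L, 1001L),
                   end = c(200L, 622L, 1400L)),
        coding_start_exon = 1L),
      primers = PrimerPair(forward = c(138L, 159L),
                           reverse = c(1124L, 1146L), chrom = "chrK"),
      editing = list(sg_target_exon = 2L)),
    ctnnb1 = list(
      model = GeneModel("Ctnnb1", "chrC", "+",
        data.frame(label = 2:7,
                   start = c(1L, 401L, 901L, 1301L, 1601L, 2001L),
                   end = c(150L, 628L, 1084L, 1399L, 1750L, 2200L)),
        coding_start_exon = 2L),
      primers = PrimerPair(forward = c(21L, 42L),
                           reverse = c(1340L, 1361L), chrom = "chrC"),
      editing = list(
        sg1_cut = list(exon = 3L, offset = 97L, genomic = 497L),
        deletion_832 = c(start = 160L, end = 991L))),
    dmd = list(
      model = GeneModel("Dmd", "chrD", "+",
        data.frame(label = 22:24,
                   start = c(1L, 1001L, 2001L),
                   end = c(300L, 1213L, 2300L)),
        coding_start_exon = 22L),
      primers = PrimerPair(forward = c(209L, 230L),
                           reverse = c(2027L, 2048L), chrom = "chrD"),
      editing = list(sg_target_exon = 23L)),
    p65 = list(
      model = GeneModel("p65", "chrP", "+",
        data.frame(label = 4:8,
                   start = c(1L, 1001L, 1501L, 2101L, 3001L),
                   end = c(150L, 1100L, 1600L, 2200L, 3150L)),
        coding_start_exon = 4L),
      primers = NULL,
      editing = list(sg_target_exon = 6L,
                     deletion_2268 = c(start = 400L, end = 2667L))),
    stop("no such fixture: ", name))
}

#' Names of the packaged fixtures
#' @return Character vector of fixture names accepted by [build_fixture()].
#' @export
fixture_names <- function() c("kras", "ctnnb1", "dmd", "p65")
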
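---
title: "Quantifying and interpreting CRISPR-induced exon skipping"
author: "skipquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and interpreting CRISPR-induced exon skipping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skipquant)
```

## The problem

A CRISPR "knockout" is usually scored by finding frameshift indels at the
target site. But an indel that lands in an exonic splicing enhancer, or
near a splice site, can cause the edited exon to be skipped from the
mature mRNA; and a single guide can induce deletions of hundreds to
thousands of base pairs that remove whole exons from the genome. In both
cases the cell produces a transcript without the targeted exon. If the
skipped length is a multiple of three, the downstream reading frame is
preserved and the protein may retain (or even gain) function — the
knockout silently fails. `skipquant` implements the quantitative analyses
needed to detect and interpret these events from RNA-seq junction reads,
amplicon deep sequencing, and genomic breakpoint data.

## The junction-count Ψ statistic

For a cassette exon *mid* flanked by *up* and *down*, with e(i,j) the
number of reads spanning the i–j junction,

$$\Psi = \frac{e_{up,mid} + e_{mid,down}}
             {e_{up,mid} + e_{mid,down} + e_{up,down}}.$$

`count_junction_reads()` produces the e(i,j) from spliced alignments: a
read supports junction (i,j) when one aligned block ends exactly at exon
i's last base and the next begins exactly at exon j's first base, with at
least `min_overhang` aligned nucleotides on both sides. The default
overhang of 6 nt is a compromise: small enough to keep most of a 75-nt
read's junction positions usable, large enough that a handful of matching
bases cannot mimic a splice. Junctions that touch no annotated exon
boundary are gathered under `novel:` keys and reported rather than
dropped — deletion-derived fusion transcripts (an intron stub spliced to a
truncated exon) surface exactly there. Deduplication, when requested,
collapses reads with identical (chromosome, start, CIGAR); this is the
single-end approximation of duplicate-pair removal.

### Estimator versus statistic

Ψ as defined above is a *reporting statistic*, kept verbatim because it is
how percent inclusion is conventionally printed. As an estimator of the
inclusion-isoform fraction w it is biased, for two reasons: inclusion is
evidenced by two junctions but exclusion by one, and a read lands on any
given junction at a rate inversely proportional to the isoform's mRNA
length. Under uniform read placement the statistic's population value is

$$\Psi(w) = \frac{2wa}{2wa + (1-w)b}, \qquad
  a = \frac{1}{L_{in}-r+1},\; b = \frac{1}{L_{ex}-r+1},$$

with r the read length and L the isoform mRNA lengths; at w = 0.64 on the
packaged Kras-like locus this is ≈ 0.74. The package therefore carries
both directions explicitly:

* `estimate_inclusion_weight()` inverts the geometry — inclusion counts
  are halved (averaged over their two junctions) and each side weighted by
  its isoform's number of valid read start positions — and converges to w.
* `inclusion_weight_for_psi()` solves Ψ(w) = ψ for w, so a simulation can
  be parameterised to emulate a clone whose *measured* Ψ equals a given
  value.

Recovery tests assert both: the statistic reproduces its target value, and
the corrected estimator recovers the generating mixture weight with bias
below 0.02 at depth 10⁴.

## Bayesian event calling

Each sample's inclusion evidence is x inclusion-junction reads out of m
informative reads. With a Beta(α, β) prior (uniform by default) the
posterior is Beta(x+α, m−x+β); `estimate_psi_posterior()` reports the
posterior mean and the central 95% interval. ΔΨ between clone and parent
is taken on posterior means so it remains defined at zero counts.

Differential splicing is scored with an analytic two-model Bayes factor:
under H1, each sample has its own uniform-prior Ψ; under H0 they share
one. Both marginal likelihoods are beta-function normalising constants,
giving the closed form used by `bayes_factor()` (computed on the log
scale, symmetric in the samples). This replaces sampler-based isoform
models: on pure inclusion/exclusion junction counts the conjugate form is
exact, fast, and fully reproducible.

An event passes `call_events()` when all three stringent filters hold:
|ΔΨ| ≥ 0.2, at least 10 informative reads in *both* samples (the
conservative reading of a total-reads filter), and BF ≥ 10. No
multiple-testing correction is applied; raw Bayes factors are reported so
users can post-filter. Calibration properties are part of the test suite:
under the null fewer than 5% of depth-100 comparisons reach BF ≥ 10, at
ΔΨ = 0.5 and depth 100 more than 80% pass all three filters, and the 95%
credible intervals cover the true Ψ at 0.95 ± 0.03.

## Amplicon indel spectra

`call_indels()` takes alignments over an amplicon reference, walks the
CIGARs, and collects insertion/deletion operations; substitutions can
never create an indel row. Each indel is left-aligned — shifted to its
lowest compatible coordinate, the same normalisation VCF uses — so that an
aligner's arbitrary placement inside a homopolymer collapses to one
allele row (the operation is idempotent, which the tests assert).
Deletions are keyed by their first deleted base; insertions by the anchor
base immediately 5′ of the inserted sequence. The Cas9 convention (blunt
cut between protospacer positions 17 and 18, 3 nt 5′ of the PAM) is
carried as metadata so positions are unambiguous.

The default minimum reported allele frequency is 0.5%, a guard against
error-prone alignments of real data; with the packaged simulator the
filter's only visible effect is to hide the rare alleles created when a
substitution error lands inside an inserted base, so exactness tests
compare unfiltered tables. Guides are classified strong when the edited
fraction strictly exceeds 20%. A convenience aligner for raw reads wraps
global pairwise alignment with pinned scoring (match +2, mismatch −3, gap
cost 5 for the first base plus 1 per additional base); aligned SAM input
is the primary path.

## Consequence prediction

`frame_report()` applies the mod-3 rule to the summed length of skipped
internal exons. For a frameshifting skip with a genome sequence supplied,
it scans the transcript 3′ of the skip junction for the first ATG in the
annotated reading frame — the candidate for translation reinitiation that
would produce a severely N-terminally truncated protein. No Kozak-context
scoring is attempted.

`predict_amplicon_size()` works in exon-label space, not genomic space:
the forward primer's exon remainder, plus the isoform's intervening exon
lengths, plus the reverse primer's exon prefix. The same arithmetic
therefore serves normal, skipped, and deletion-derived isoforms, and
satisfies the identity full − skipped = skipped-exon length whenever the
primers flank the cassette (property-tested on random gene models).

`interpret_deletion()` annotates a breakpoint interval: lesion length,
exons contained entirely within it, and breakpoint context. With both
breakpoints intronic, the nearest surviving upstream exon is predicted to
splice to the nearest surviving downstream exon; an exonic breakpoint
yields a fusion description (e.g. an intron-2 stub joined to the remainder
of exon 4). This nearest-exon rule is a deliberate simplification — splice
site strength is not modelled, and empirically observed junctions always
take precedence over the prediction.

## The simulators and what they do (not) emulate

All generators are pure functions of their inputs and a seed, and every
output is paired with a truth table; downstream tests only accept
simulator output together with its truth.

* `simulate_junction_reads()` draws an isoform by mixture weight and a
  start uniformly along its mRNA, emitting spliced SAM records whose M/N
  blocks match the genomic exon structure. There is no fragment-length
  model, no paired ends, no coverage bias: junction counting is the only
  consumer. The truth table's per-junction counts are computed by interval
  arithmetic on the placements, independent of the CIGAR path, and a
  brute-force per-base enumeration oracle backs both in the tests.
* `simulate_amplicon_reads()` gives every read the full amplicon carrying
  one spectrum allele plus substitution errors; insertions sit between cut
  and cut+1, deletions remove bases starting at cut+1. No PCR bias,
  chimeras, or duplication artifacts (duplicates are injected only by an
  explicit flag, to exercise deduplication).
* `simulate_genome_sequence()` plants a stop-free coding stream across the
  exons (ATG at the coding start, TAA as the final codon, canonical GT/AG
  intron ends) so frame predictions can be checked against brute-force
  translation; an extra in-frame ATG can be planted to probe the
  downstream-start scan.
* `simulate_gene_counts()` uses negative-binomial noise with dispersion
  0.005 — the scale expected for a deeply sequenced, highly expressed
  gene; replicate numbers default to the small-n design typical of such
  experiments (two to three per group). Because a single n = 2–3
  experiment carries several percentage points of sampling noise, recovery
  of a generating reduction is assessed as the mean estimate over many
  simulated experiments (a bias check), not from one draw.

Passing tests on these simulators demonstrate correctness of the counting,
estimation, and interpretation machinery under the stated generative
assumptions. They do not demonstrate robustness to alignment artifacts,
coverage non-uniformity, degraded RNA, or PCR chimeras in real libraries.

## Numerical choices and degenerate inputs

* Zero informative junction reads: Ψ is flagged undefined (`NA` with a
  warning), never 0/0.
* x = m = 0 with a uniform prior returns the prior itself (mean 0.5,
  interval 0.025–0.975).
* The Bayes factor is evaluated via `lbeta` throughout; counts in the
  thousands cause no overflow.
* Exon labels need not start at 1 and may describe a sub-locus; minus
  strand models are handled by coordinate reflection, with labels
  increasing 5′→3′.
* Problem sizes in the routine suites: junction simulations at depths
  400–10⁴, 200 posterior-coverage draws at depth 2000, 500 calibration
  and power draws at depth 100, amplicon spectra at depth 2000–5000, and
  150 repetitions of the count-reduction experiments — the full test suite
  runs in about a minute on one CPU.

## Limitations

* Junction reads only: no exon-body coverage model, so Ψ estimates at very
  low depth rest on few informative reads (the posterior interval makes
  that visible).
* The nearest-exon splice prediction for deletion alleles ignores splice
  site strength and branch-point context.
* The promiscuous multi-exon skipping ladder (one donor spliced to several
  downstream acceptors) is reported via `donor_usage_fractions()` but not
  mechanistically modelled.
* No NMD-efficiency model: the expression-change computation quantifies
  the observed reduction, not the expected decay of a frameshifted
  transcript.
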
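#' Beta-binomial posterior for PSI
#'
#' Conjugate update of a Beta(alpha, beta) prior on the inclusion fraction
#' by `x_inclusion` inclusion-supporting reads out of `m_total` informative
#' junction reads. The point estimate `psi` is the raw ratio; the
#' posterior mean and central 95% credible interval come from
#' Beta(x + alpha, m - x + beta).
#'
#' @param x_inclusion Inclusion-junction read count.
#' @param m_total Total informative junction reads.
#' @param prior Length-2 vector `c(alpha, beta)`; default uniform `c(1,1)`.
#' @param ci_level Credible-interval mass (default 0.95).
#' @return An object of class `PsiEstimate`: list with `psi`,
#'   `x_inclusion`, `m_total`, `posterior_mean`, `ci_low`, `ci_high`.
#' @examples
#' estimate_psi_posterior(128, 200)$posterior_mean  # 129/202
#' @export
estimate_psi_posterior <- function(x_inclusion, m_total, prior = c(1, 1),
                                   ci_level = 0.95) {
  x <- as.integer(x_inclusion); m <- as.integer(m_total)
  if (x < 0L || m < 0L || x > m) stop("invalid counts: need 0 <= x <= m")
  a <- prior[1L] + x
  b <- prior[2L] + m - x
  tail <- (1 - ci_level) / 2
  structure(list(
    psi = if (m > 0L) x / m else NA_real_,
    x_inclusion = x, m_total = m,
    posterior_mean = a / (a + b),
    ci_low = stats::qbeta(tail, a, b),
    ci_high = stats::qbeta(1 - tail, a, b)),
    class = "PsiEstimate")
}

#' @export
print.PsiEstimate <- function(x, ...) {
  cat(sprintf("PSI %s (%d/%d), posterior mean %.3f, 95%% CI [%.3f, %.3f]\n",
              ifelse(is.na(x$psi), "NA", sprintf("%.3f", x$psi)),
              x$x_inclusion, x$m_total, x$posterior_mean, x$ci_low,
              x$ci_high))
  invisible(x)
}

#' Bayes factor for differential PSI between two samples
#'
#' Analytic two-model comparison on inclusion/total junction-read counts:
#' H1 puts independent uniform priors on PSI in each sample, H0 a single
#' shared uniform PSI. Both marginal likelihoods are available in closed
#' form from beta-function normalising constants, giving
#'
#' \deqn{BF = \frac{B(x_a+1, m_a-x_a+1)\,B(x_b+1, m_b-x_b+1)}
#'                 {B(x_a+x_b+1, m_a+m_b-x_a-x_b+1)}}
#'
#' evaluated on the log scale. BF > 1 favours different PSI; the
#' conventional event-calling threshold is BF >= 10. The statistic is
#' symmetric in the two samples.
#'
#' @param x_a,m_a Inclusion and total counts in sample A.
#' @param x_b,m_b Inclusion and total counts in sample B.
#' @return The Bayes factor (positive scalar).
#' @export
bayes_factor <- function(x_a, m_a, x_b, m_b) {
  stopifnot(x_a >= 0, x_b >= 0, x_a <= m_a, x_b <= m_b)
  exp(lbeta(x_a + 1, m_a - x_a + 1) + lbeta(x_b + 1, m_b - x_b + 1) -
        lbeta(x_a + x_b + 1, m_a + m_b - x_a - x_b + 1))
}

#' Call differential splicing events between clone and parent
#'
#' For every cassette exon, compares the clone's and parent's
#' junction-read counts: posterior PSI in each sample
#' ([estimate_psi_posterior()]), their difference (delta PSI, on posterior
#' means so it stays defined at low counts), and the closed-form
#' [bayes_factor()]. An event passes when all three stringent filters
#' hold: `|delta PSI| >= delta_min`, both samples have at least
#' `reads_min` informative reads, and `BF >= bf_min`. Defaults are the
#' conventional stringent cutoffs (0.2, 10, 10). No multiple-testing
#' correction is applied; raw Bayes factors are reported so users can
#' post-filter.
#'
#' @param clone,parent `data.frame`s with columns `gene`, `cassette`,
#'   `x` (inclusion count) and `m` (total count); the two must describe
#'   the same (gene, cassette) set.
#' @param delta_min,reads_min,bf_min Filter thresholds.
#' @param prior Beta prior passed to [estimate_psi_posterior()].
#' @return `data.frame` of `SpliceEvent` rows: `gene`, `cassette`,
#'   `psi_parent`, `psi_clone` (posterior means), `delta_psi`
#'   (clone - parent), `reads_parent`, `reads_clone`, `bayes_factor`,
#'   `passes`.
#' @export
call_events <- function(clone, parent, delta_min = 0.2, reads_min = 10,
                        bf_min = 10, prior = c(1, 1)) {
  key_c <- paste(clone$gene, clone$cassette)
  key_p <- paste(parent$gene, parent$cassette)
  if (length(key_c) != length(key_p) || !setequal(key_c, key_p) ||
      anyDuplicated(key_c) || anyDuplicated(key_p))
    stop("sample mismatch: clone and parent cassette sets differ")
  parent <- parent[match(key_c, key_p), , drop = FALSE]
  n <- nrow(clone)
  out <- data.frame(gene = clone$gene, cassette = clone$cassette,
                    psi_parent = NA_real_, psi_clone = NA_real_,
                    delta_psi = NA_real_,
                    reads_parent = parent$m, reads_clone = clone$m,
                    bayes_factor = NA_real_, passes = FALSE)
  for (i in seq_len(n)) {
    pp <- estimate_psi_posterior(parent$x[i], parent$m[i], prior)
    pc <- estimate_psi_posterior(clone$x[i], clone$m[i], prior)
    bf <- bayes_factor(parent$x[i], parent$m[i], clone$x[i], clone$m[i])
    out$psi_parent[i] <- pp$posterior_mean
    out$psi_clone[i] <- pc$posterior_mean
    out$delta_psi[i] <- pc$posterior_mean - pp$posterior_mean
    out$bayes_factor[i] <- bf
    out$passes[i] <- abs(out$delta_psi[i]) >= delta_min &&
      min(parent$m[i], clone$m[i]) >= reads_min && bf >= bf_min
  }
  out
}

#' Replicate summary of PSI values on the percent scale
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' per-replicate PSI fractions, reported as percentages ("% exon
#' inclusion, mean +/- s.d.").
#'
#' @param psi Numeric vector of PSI fractions in `[0, 1]`; at least one.
#' @return List with `mean_percent` and `sd_percent` (`NA` for a single
#'   replicate).
#' @examples
#' replicate_summary(c(0.60, 0.64, 0.68))  # 64.0 +/- 4.0
#' @export
replicate_summary <- function(psi) {
  if (length(psi) == 0L) stop("no replicates")
  list(mean_percent = 100 * mean(psi),
       sd_percent = if (length(psi) > 1L) 100 * stats::sd(psi) else NA_real_)
}

#' Events shared between two clones
#'
#' Intersects the passing events of two clone-vs-parent comparisons,
#' matching on (gene, cassette) and requiring the same direction of
#' change (sign of delta PSI): an exon more included in one clone and more
#' skipped in the other is not a shared event.
#'
#' @param events_a,events_b Event tables from [call_events()].
#' @return `data.frame` with `gene`, `cassette`, `direction`
#'   (`"inclusion"` or `"exclusion"`).
#' @export
shared_events <- function(events_a, events_b) {
  pa <- events_a[events_a$passes, , drop = FALSE]
  pb <- events_b[events_b$passes, , drop = FALSE]
  key_a <- paste(pa$gene, pa$cassette)
  key_b <- paste(pb$gene, pb$cassette)
  common <- intersect(key_a, key_b)
  ia <- match(common, key_a); ib <- match(common, key_b)
  same <- sign(pa$delta_psi[ia]) == sign(pb$delta_psi[ib])
  data.frame(gene = pa$gene[ia][same], cassette = pa$cassette[ia][same],
             direction = ifelse(pa$delta_psi[ia][same] > 0,
                                "inclusion", "exclusion"),
             row.names = NULL)
}
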
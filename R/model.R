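#' Kimura fixation-rate ratio
#'
#' Under weak selection the fixation probability of a new allele with
#' population-scaled selection coefficient S = 4Nes is
#' u(s) = (1/2N) S / (1 - exp(-S)); relative to a neutral allele with the same
#' mutation rate the substitution-rate ratio is therefore
#' r(S) = S / (1 - exp(-S)). The ratio is strictly increasing, positive for
#' all finite S, and satisfies r(S) - r(-S) = S; the removable singularity at
#' S = 0 (r = 1) is evaluated by series expansion.
#'
#' @param S numeric vector of 4Nes values.
#' @return numeric vector of rate ratios.
#' @examples
#' fixationRatio(0)   # 1
#' fixationRatio(1)   # 1.58198
#' fixationRatio(-2)  # 0.31304
#' @export
fixationRatio <- function(S) {
  stopifnot(is.numeric(S), all(is.finite(S)))
  r <- numeric(length(S))
  small <- abs(S) < 1e-5
  s <- S[small]
  # S/(1 - e^-S) = 1 + S/2 + S^2/12 - S^4/720 + ...
  r[small] <- 1 + s / 2 + s^2 / 12 - s^4 / 720
  s <- S[!small]
  r[!small] <- ifelse(s > 0, s / (-expm1(-s)), s * exp(s) / expm1(s))
  r
}

fixationRatioDeriv <- function(S) {
  small <- abs(S) < 1e-5
  d <- numeric(length(S))
  d[small] <- 0.5 + S[small] / 6
  s <- S[!small]
  em <- expm1(-s)            # e^-S - 1
  d[!small] <- (-em - s * (em + 1)) / em^2
  d
}

#' Recover 4Nes from a substitution-rate ratio
#'
#' Numerically inverts [fixationRatio()]: given the ratio r of the observed to
#' the neutrally expected substitution frequency, finds the unique S with
#' S / (1 - exp(-S)) = r. Bracketed root-finding (expanding from \[-100, 100\]
#' if needed) followed by Newton polishing; the round trip through
#' `fixationRatio` is accurate to better than 1e-8.
#'
#' @param r numeric vector of positive rate ratios.
#' @return numeric vector of 4Nes values.
#' @examples
#' invertRateRatio(1)        # 0
#' invertRateRatio(1.58198)  # ~1
#' invertRateRatio(0.5)      # ~ -1.256
#' @export
invertRateRatio <- function(r) {
  stopifnot(is.numeric(r))
  vapply(r, function(ri) {
    if (!is.finite(ri) || ri <= 0)
      stop("rate ratio must be finite and > 0 (got ", ri, ")")
    if (abs(ri - 1) < 1e-14) return(0)
    lo <- -100; hi <- 100
    while (fixationRatio(lo) > ri) lo <- lo * 2
    while (fixationRatio(hi) < ri) hi <- hi * 2
    S <- uniroot(function(s) fixationRatio(s) - ri, c(lo, hi),
                 tol = 1e-12)$root
    for (i in 1:3) {  # Newton polish to |delta r| < 1e-10
      S <- S - (fixationRatio(S) - ri) / fixationRatioDeriv(S)
    }
    S
  }, numeric(1))
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Central exact interval obtained by inverting the binomial tails (beta
#' quantile form). The lower bound is 0 when k = 0 and the upper bound is 1
#' when k = n. Coverage is conservative (at least the nominal level).
#'
#' @param k number of successes (vectorized).
#' @param n number of trials.
#' @param alpha two-sided error rate (default 0.05).
#' @return matrix with columns `lo`, `hi`.
#' @examples
#' clopperPearson(0, 10)  # hi = 1 - 0.025^(1/10) = 0.3085
#' @export
clopperPearson <- function(k, n, alpha = 0.05) {
  if (any(n <= 0) || any(k < 0) || any(k > n) || any(k != round(k)))
    stop("require integer 0 <= k <= n, n > 0")
  lo <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
  hi <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  cbind(lo = lo, hi = hi)
}

#' Estimate 4Nes from observed and neutrally expected substitution frequencies
#'
#' The point estimate inverts the Kimura rate ratio at r = q / qExp where
#' q = k/n is the observed class-exit frequency. Confidence limits transform
#' the Clopper-Pearson limits of q through the same inversion, treating the
#' neutral control as error-free (its sampling error is assumed negligible).
#' When the lower frequency limit is 0 the lower 4Nes limit is -Inf
#' (open-ended); when k = 0 the point estimate itself is -Inf.
#'
#' @param k observed substitution count.
#' @param n observed opportunity count (conserved + substituted).
#' @param qExp neutrally expected frequency (> 0).
#' @param alpha two-sided error rate for the interval.
#' @return one-row data.frame: k, n, q, ciLow, ciHigh (frequency scale),
#'   r, SHat, SLow, SHigh.
#' @export
estimateSelection <- function(k, n, qExp, alpha = 0.05) {
  if (n == 0) stop("undefined: no opportunities (n = 0)")
  if (!is.finite(qExp) || qExp <= 0) stop("qExp must be > 0")
  q <- k / n
  ci <- clopperPearson(k, n, alpha)
  r <- q / qExp
  SHat <- if (k == 0) -Inf else invertRateRatio(r)
  SLow <- if (ci[1, "lo"] == 0) -Inf else invertRateRatio(ci[1, "lo"] / qExp)
  SHigh <- if (ci[1, "hi"] == 0) -Inf else invertRateRatio(ci[1, "hi"] / qExp)
  data.frame(k = k, n = n, q = q, ciLow = ci[1, "lo"], ciHigh = ci[1, "hi"],
             qExp = qExp, r = r, SHat = SHat, SLow = SLow, SHigh = SHigh)
}

#' Per-locus selection coefficient from 4Nes
#'
#' @param S population-scaled selection coefficient 4Nes.
#' @param Ne effective population size (> 0), e.g. ~1e4 for human,
#'   ~1e6 for *Drosophila*.
#' @return s = S / (4 Ne).
#' @examples
#' perLocusS(1, 1e4)  # 2.5e-5
#' perLocusS(1, 1e6)  # 2.5e-7
#' @export
perLocusS <- function(S, Ne) {
  if (any(Ne <= 0)) stop("Ne must be > 0")
  S / (4 * Ne)
}

#' Drift load from suboptimal splice-site nucleotides
#'
#' Summed selection coefficient against all nonconsensus alleles across an
#' ensemble of splice sites: load = nSS * meanNc * sPerLocus.
#'
#' @param nSS number of splice sites.
#' @param meanNc mean number of Nc nucleotides per site.
#' @param sPerLocus per-locus selection coefficient against an Nc allele.
#' @return one-row data.frame with nSS, meanNc, sPerLocus and load.
#' @examples
#' driftLoad(150000, 7.10, 2e-5)$load  # 21.3
#' @export
driftLoad <- function(nSS, meanNc, sPerLocus) {
  if (any(c(nSS, meanNc, sPerLocus) < 0)) stop("inputs must be non-negative")
  data.frame(nSS = nSS, meanNc = meanNc, sPerLocus = sPerLocus,
             load = nSS * meanNc * sPerLocus)
}

#' Mean Nc count and Cn fraction of an ensemble
#'
#' Over the scored offsets of the ensemble's site type, counts how many
#' positions of each reference sequence carry a nonconsensus nucleotide, and
#' the complementary fraction of positions occupied by consensus nucleotides.
#'
#' @param ensemble a [SpliceSiteEnsemble-class].
#' @param consensus a [ConsensusTable-class].
#' @return list with `meanNc`, `cnFraction`, `nScored`.
#' @export
ncSummary <- function(ensemble, consensus) {
  st <- ensemble@siteType
  offs <- scoredOffsets(consensus, st)
  idx <- match(offs, ensemble@offsets)
  m <- ensemble@seqs$ref[, idx, drop = FALSE]
  isCn <- matrix(FALSE, nrow(m), ncol(m))
  for (j in seq_along(offs)) {
    cn <- match(cnSet(consensus, st, offs[j]), NUC)
    isCn[, j] <- m[, j] %in% cn
  }
  list(meanNc = mean(rowSums(!isCn)), cnFraction = mean(isCn),
       nScored = length(offs))
}
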
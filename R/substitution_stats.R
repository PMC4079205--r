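## Class-level substitution frequencies and neutral expectations.

classSets <- function(consensus, siteType, offset, direction) {
  cn <- match(cnSet(consensus, siteType, offset), NUC)
  if (!length(cn)) stop("offset ", offset, " has no defined Cn set (role ",
                        positionRole(siteType, offset), ")")
  nc <- setdiff(1:4, cn)
  if (direction == "CnToNc") list(from = cn, to = nc)
  else list(from = nc, to = cn)
}

#' Observed class-exit substitution frequency q at one position
#'
#' For direction Cn->Nc, q = k/n with k the count of columns whose ancestor is
#' a Cn nucleotide and whose descendant lies outside the Cn set, and n the
#' count of all columns with a Cn ancestor (conserved and substituted;
#' within-class moves such as Cn->Cn when |Cn| = 2 count toward n but not k).
#' The symmetric definition applies to Nc->Cn. The 95% interval is exact
#' Clopper-Pearson.
#'
#' @param counts a [SubstitutionCounts-class].
#' @param consensus a [ConsensusTable-class].
#' @param offset signed offset with a defined Cn set.
#' @param direction `"CnToNc"` or `"NcToCn"`.
#' @param alpha two-sided error rate for the interval.
#' @return one-row data.frame: siteType, offset, direction, k, n, q, ciLow,
#'   ciHigh.
#' @export
classFrequency <- function(counts, consensus, offset,
                           direction = c("CnToNc", "NcToCn"), alpha = 0.05) {
  direction <- match.arg(direction)
  cls <- classSets(consensus, counts@siteType, offset, direction)
  m <- countMatrix(counts, offset)
  k <- sum(m[cls$from, cls$to])
  n <- sum(m[cls$from, ])
  q <- if (n > 0) k / n else NA_real_
  ci <- if (n > 0) clopperPearson(k, n, alpha) else cbind(lo = NA_real_, hi = NA_real_)
  data.frame(siteType = counts@siteType, offset = offset,
             direction = direction, k = k, n = n, q = q,
             ciLow = ci[1, "lo"], ciHigh = ci[1, "hi"])
}

#' Neutrally expected class-exit frequency at one position
#'
#' Applies the observed ancestral composition of the position's source class
#' to the nucleotide-matched neutral control rates: qExp = sum_Z w_Z r_Z(T)
#' where Z runs over the class members, w_Z is the ancestral composition
#' weight at this offset and T is the complementary class. Intronic offsets
#' use the intronic controls and exonic offsets the 4-fold degenerate
#' controls. Expected counts scale qExp by the observed opportunity.
#'
#' @inheritParams classFrequency
#' @param neutral a [NeutralRates-class].
#' @return one-row data.frame: qExp, kExp, nExp, kCtl, nCtl (raw control
#'   class counts for exact testing), provenance.
#' @export
expectedFrequency <- function(counts, consensus, offset, direction,
                              neutral) {
  direction <- match.arg(direction, c("CnToNc", "NcToCn"))
  st <- counts@siteType
  cls <- classSets(consensus, st, offset, direction)
  prov <- if (roleOf(st, offset) == "intronic") "intronic" else "fourfold"
  m <- countMatrix(counts, offset)
  w <- rowSums(m)[cls$from]
  if (sum(w) == 0)
    stop("no ancestral class members observed at offset ", offset)
  rates <- vapply(cls$from, function(z)
    neutralRate(neutral, prov, NUC[z], NUC[cls$to])$rate, numeric(1))
  qExp <- sum(w * rates) / sum(w)
  nObs <- sum(m[cls$from, ])
  ctl <- neutral@counts[[prov]]
  data.frame(qExp = qExp, kExp = qExp * nObs, nExp = nObs,
             kCtl = sum(ctl[cls$from, cls$to]), nCtl = sum(ctl[cls$from, ]),
             provenance = prov)
}

#' Exact test of observed versus neutrally expected substitution counts
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' {substituted, conserved} x {splice site, control}.
#'
#' @param kObs,nObs observed substitution and opportunity counts.
#' @param kExp,nExp control substitution and opportunity counts.
#' @return two-sided p-value.
#' @export
obsVsExpTest <- function(kObs, nObs, kExp, nExp) {
  stopifnot(kObs >= 0, kExp >= 0, nObs >= kObs, nExp >= kExp)
  tab <- matrix(round(c(kObs, nObs - kObs, kExp, nExp - kExp)), 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero margin); p = 1")
    return(1)
  }
  fisher.test(tab)$p.value
}

#' Per-offset selection table
#'
#' The workhorse of the inference pipeline: for every scored offset and both
#' substitution directions, computes the observed frequency q with its
#' Clopper-Pearson interval, the nucleotide-matched neutral expectation qExp,
#' Fisher's exact p-value for obs vs control, a Benjamini-Hochberg adjusted
#' column (extension; the raw p mirrors the per-offset reporting), and the
#' 4Nes estimate with its 95% interval from [estimateSelection()].
#'
#' @param counts a [SubstitutionCounts-class].
#' @param consensus a [ConsensusTable-class].
#' @param neutral a [NeutralRates-class].
#' @param alpha two-sided error rate.
#' @return data.frame with one row per offset x direction.
#' @export
selectionTable <- function(counts, consensus, neutral, alpha = 0.05) {
  offs <- intersect(scoredOffsets(consensus, counts@siteType), counts@offsets)
  rows <- list()
  for (o in offs) for (dir in c("CnToNc", "NcToCn")) {
    obs <- classFrequency(counts, consensus, o, dir, alpha)
    if (obs$n == 0) next  # no ancestral class members at this offset
    exp <- expectedFrequency(counts, consensus, o, dir, neutral)
    p <- obsVsExpTest(obs$k, obs$n, exp$kCtl, exp$nCtl)
    est <- if (obs$n > 0 && exp$qExp > 0)
      estimateSelection(obs$k, obs$n, exp$qExp, alpha)[, c("r", "SHat", "SLow", "SHigh")]
    else data.frame(r = NA_real_, SHat = NA_real_, SLow = NA_real_,
                    SHigh = NA_real_)
    rows[[length(rows) + 1L]] <-
      cbind(obs, exp[, c("qExp", "provenance")], pFisher = p, est)
  }
  out <- do.call(rbind, rows)
  out$pBH <- p.adjust(out$pFisher, "BH")
  rownames(out) <- NULL
  out
}

#' Pooled selection estimate across offsets
#'
#' Pools substitution and opportunity counts over the scored offsets (per
#' direction) and weights the neutral expectation by each offset's ancestral
#' class composition and provenance-specific control rates, then estimates a
#' single 4Nes for the pooled class-exit frequency.
#'
#' @inheritParams selectionTable
#' @param direction `"CnToNc"` or `"NcToCn"`.
#' @return one-row data.frame as returned by [estimateSelection()].
#' @export
pooledSelection <- function(counts, consensus, neutral,
                            direction = c("CnToNc", "NcToCn"), alpha = 0.05) {
  direction <- match.arg(direction)
  offs <- intersect(scoredOffsets(consensus, counts@siteType), counts@offsets)
  k <- 0; n <- 0; kE <- 0
  for (o in offs) {
    obs <- classFrequency(counts, consensus, o, direction, alpha)
    exp <- expectedFrequency(counts, consensus, o, direction, neutral)
    k <- k + obs$k; n <- n + obs$n; kE <- kE + exp$qExp * obs$n
  }
  if (n == 0) stop("no opportunities in any offset")
  estimateSelection(k, n, kE / n, alpha)
}
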
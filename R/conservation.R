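## Multispecies conservation depth and the (obs - exp)/exp contrast.

#' Conservation depth of alignment columns
#'
#' For each column, the depth L is the phylogenetic distance (Ks) of the most
#' distant species x such that the target nucleotide set is observed in every
#' species i with L(r, i) <= L(r, x). If the nearest species already fails,
#' L = 0. Missing data terminates the conserved prefix, and when several
#' species sit at a tied distance, all of them must match for that distance
#' to count.
#'
#' @param states integer or character matrix, one row per column and one
#'   column per panel species ordered by non-decreasing distance.
#' @param distances numeric non-decreasing Ks distances from the reference.
#' @param target a vector of nucleotides shared by all columns (set
#'   selector), or, with `perColumn = TRUE`, one target nucleotide per column
#'   (nuc selector; typically the column's reference nucleotide).
#' @param perColumn logical; interpret `target` as one nucleotide per column.
#' @return numeric vector of depths, one per column.
#' @export
conservationDepth <- function(states, distances, target, perColumn = FALSE) {
  if (!nrow(states)) stop("empty panel")
  if (is.unsorted(distances)) stop("distances must be non-decreasing")
  S <- length(distances)
  stopifnot(ncol(states) == S)
  if (is.character(states)) states <- matrix(match(toupper(states), NUC),
                                             nrow(states), ncol(states))
  if (!length(target)) stop("target set must be non-empty")
  if (is.character(target)) target <- match(toupper(target), NUC)
  if (perColumn && length(target) != nrow(states))
    stop("per-column target must have one entry per column")
  M <- if (perColumn) states == target  # recycles per-column target by row
  else matrix(states %in% target, nrow(states), S)
  M[is.na(M)] <- FALSE
  # effective depth of a prefix ending at species j, honouring distance ties
  eff <- distances
  for (j in seq_len(S - 1))
    if (distances[j + 1] == distances[j])
      eff[j] <- max(0, distances[distances < distances[j]])
  depthIdx <- integer(nrow(M))
  alive <- rep(TRUE, nrow(M))
  for (j in seq_len(S)) {
    alive <- alive & M[, j]
    depthIdx[alive] <- j
  }
  c(0, eff)[depthIdx + 1L]
}

#' Conservation contrast c = (obs - exp) / exp
#'
#' Compares the mean conservation depth of splice-site columns whose reference
#' nucleotide belongs to the queried class (`cn` or `nc`) against matched
#' neutral control columns. With `selector = "nuc"` the target is the specific
#' reference nucleotide of each column; with `selector = "set"` it is the full
#' class set of the offset. The neutral expectation matches controls by
#' reference nucleotide identity: exp is the composition-weighted mean of the
#' per-nucleotide control depths, weighted by the observed reference
#' composition. Percentile bootstrap intervals resample observed and matched
#' control columns jointly in each of B trials.
#'
#' @param panel a [PanelEnsemble-class] of splice-site columns.
#' @param control a [PanelEnsemble-class] of neutral control columns.
#' @param consensus a [ConsensusTable-class].
#' @param offset signed offset to analyse.
#' @param class `"cn"` or `"nc"`: which nucleotide class the reference state
#'   must belong to.
#' @param selector `"nuc"` or `"set"`.
#' @param B bootstrap trials (default 1000); `B = 0` skips the interval.
#' @param seed optional seed for the bootstrap resampling.
#' @return one-row data.frame: offset, class, selector, obs, exp, c, ciLow,
#'   ciHigh, n.
#' @export
conservationContrast <- function(panel, control, consensus, offset,
                                 class = c("nc", "cn"),
                                 selector = c("nuc", "set"), B = 1000,
                                 seed = NULL) {
  class <- match.arg(class)
  selector <- match.arg(selector)
  j <- match(offset, panel@offsets)
  if (is.na(j)) stop("offset ", offset, " not in panel")
  st <- panel@siteType
  cn <- match(cnSet(consensus, st, offset), NUC)
  set <- if (class == "cn") cn else setdiff(1:4, cn)
  refs <- panel@ref[, j]
  use <- which(refs %in% set)
  if (!length(use)) stop("no columns with a ", class, " reference state")
  obsStates <- panel@species[use, j, , drop = FALSE]
  obsStates <- matrix(obsStates, length(use), length(panel@distances))
  obsRef <- refs[use]
  obsDepth <- if (selector == "nuc")
    conservationDepth(obsStates, panel@distances, obsRef, perColumn = TRUE)
  else conservationDepth(obsStates, panel@distances, set)

  ctlRef <- control@ref[, 1]
  ctlStates <- matrix(control@species[, 1, ], length(ctlRef),
                      length(control@distances))
  ctlUse <- which(ctlRef %in% set)
  if (!length(ctlUse)) stop("no matched control columns")
  ctlRefU <- ctlRef[ctlUse]
  ctlDepth <- if (selector == "nuc")
    conservationDepth(ctlStates[ctlUse, , drop = FALSE], control@distances,
                      ctlRefU, perColumn = TRUE)
  else conservationDepth(ctlStates[ctlUse, , drop = FALSE],
                         control@distances, set)

  contrastOf <- function(oDepth, oRef, cDepth, cRef) {
    obs <- mean(oDepth)
    w <- table(factor(oRef, levels = set))
    mz <- vapply(set, function(z) {
      d <- cDepth[cRef == z]
      if (!length(d)) NA_real_ else mean(d)
    }, numeric(1))
    ok <- !is.na(mz) & w > 0
    expv <- sum(w[ok] * mz[ok]) / sum(w[ok])
    if (!is.finite(expv) || expv == 0)
      stop("neutral expectation is zero; contrast undefined")
    c(obs = obs, exp = expv, c = (obs - expv) / expv)
  }
  pt <- contrastOf(obsDepth, obsRef, ctlDepth, ctlRefU)
  ciLow <- ciHigh <- NA_real_
  if (B > 0) {
    if (!is.null(seed)) set.seed(seed)
    cs <- vapply(seq_len(B), function(b) {
      oi <- sample.int(length(obsDepth), replace = TRUE)
      ci <- sample.int(length(ctlDepth), replace = TRUE)
      tryCatch(contrastOf(obsDepth[oi], obsRef[oi], ctlDepth[ci],
                          ctlRefU[ci])[["c"]],
               error = function(e) NA_real_)
    }, numeric(1))
    cs <- cs[is.finite(cs)]
    if (length(unique(cs)) == 1L)
      warning("degenerate bootstrap statistic; zero-width interval")
    qs <- quantile(cs, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
    ciLow <- qs[1]; ciHigh <- qs[2]
  }
  data.frame(siteType = st, offset = offset, class = class,
             selector = selector, obs = pt[["obs"]], exp = pt[["exp"]],
             c = pt[["c"]], ciLow = ciLow, ciHigh = ciHigh,
             n = length(obsDepth))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows (for matrices/data.frames) or elements (for vectors) with
#' replacement B times and returns the 2.5/97.5 percentile interval of the
#' statistic. Deterministic for a fixed seed.
#'
#' @param x data: vector, matrix or data.frame of alignment columns.
#' @param statistic function mapping a resample of `x` to a scalar.
#' @param B number of bootstrap trials (default 1000).
#' @param seed optional RNG seed.
#' @return named numeric `c(lo, hi)`.
#' @export
bootstrapCI <- function(x, statistic, B = 1000, seed = NULL) {
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  if (n < 2) stop("need at least 2 columns to bootstrap")
  if (!is.null(seed)) set.seed(seed)
  take <- if (is.null(dim(x))) function(i) x[i] else
    function(i) x[i, , drop = FALSE]
  stats <- vapply(seq_len(B),
                  function(b) statistic(take(sample.int(n, replace = TRUE))),
                  numeric(1))
  if (length(unique(stats)) == 1L)
    warning("degenerate bootstrap statistic; zero-width interval")
  qs <- quantile(stats, c(0.025, 0.975), names = FALSE)
  c(lo = qs[1], hi = qs[2])
}
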
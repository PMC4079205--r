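#' Maximum-parsimony ancestor of the reference/sister clade
#'
#' On the three-taxon tree ((ref, sister), outgroup), the ancestral state of
#' the (ref, sister) clade is the nucleotide minimizing the total number of
#' changes; for three taxa this is the state shared by at least two species.
#' When the minimum is tied (all three species differ) or any species has
#' missing data, the column is ambiguous.
#'
#' @param ref,sister,outgroup character vectors of A/C/G/T (or NA for
#'   missing/gap), or integer codes 1..4; vectorized.
#' @return character vector of ancestral nucleotides, NA where ambiguous.
#' @examples
#' parsimonyAncestor("A", "A", "A")  # "A"
#' parsimonyAncestor("A", "G", "G")  # "G"
#' parsimonyAncestor("A", "G", "C")  # NA (tie)
#' @export
parsimonyAncestor <- function(ref, sister, outgroup) {
  enc <- function(x) {
    if (is.numeric(x)) {
      if (any(!x %in% c(1:4, NA))) stop("integer codes must be 1..4")
      return(as.integer(x))
    }
    x <- toupper(as.character(x))
    bad <- !is.na(x) & !x %in% c(NUC, "-", "N", ".")
    if (any(bad)) stop("non-nucleotide symbol: ", x[which(bad)[1]])
    i <- match(x, NUC)  # gaps / N -> NA -> ambiguous
    i
  }
  r <- enc(ref); s <- enc(sister); o <- enc(outgroup)
  n <- max(length(r), length(s), length(o))
  r <- rep_len(r, n); s <- rep_len(s, n); o <- rep_len(o, n)
  anc <- rep(NA_integer_, n)
  ok <- !is.na(r) & !is.na(s) & !is.na(o)
  anc[ok & r == s] <- r[ok & r == s]
  anc[ok & r != s & s == o] <- s[ok & r != s & s == o]
  anc[ok & r != s & r == o] <- r[ok & r != s & r == o]
  NUC[anc]
}

#' Tabulate ancestral-to-descendant substitutions along the reference lineage
#'
#' For every non-invariant offset, reconstructs the (ref, sister) ancestor of
#' each site by maximum parsimony and increments `#(anc -> ref)`; the diagonal
#' holds conserved columns. Ambiguous reconstructions are dropped from both
#' numerator and denominator. With `excludeCpg = TRUE`, any position that is
#' part of a CG dinucleotide in the reconstructed ancestral sequence context
#' (C followed by G, or G preceded by C, on the transcribed strand) is
#' excluded; positions whose relevant neighbour is ambiguous are kept.
#'
#' @param ensemble a [SpliceSiteEnsemble-class] with ref/sister/outgroup
#'   sequences.
#' @param consensus a [ConsensusTable-class] (defines position roles).
#' @param excludeCpg logical; apply the ancestral CpG filter.
#' @return a [SubstitutionCounts-class].
#' @export
countSubstitutions <- function(ensemble, consensus = defaultConsensus(),
                               excludeCpg = FALSE) {
  st <- ensemble@siteType
  offs <- ensemble@offsets
  sq <- ensemble@seqs
  if (!all(dim(sq$ref) == dim(sq$sister)) ||
      !all(dim(sq$ref) == dim(sq$outgroup)))
    stop("species sequence matrices differ in dimension")
  K <- length(offs)
  n <- nrow(sq$ref)

  # reconstruct the full ancestral matrix once (needed for CpG context)
  anc <- matrix(match(parsimonyAncestor(as.vector(sq$ref),
                                        as.vector(sq$sister),
                                        as.vector(sq$outgroup)), NUC),
                n, K, dimnames = dimnames(sq$ref))
  roles <- vapply(offs, function(o) roleOf(st, o), "")
  keepOff <- which(roles != "invariant")
  cpg <- if (excludeCpg) cpgContext(anc, naAsWild = TRUE) else
    matrix(FALSE, n, K)

  counts <- array(0L, c(4, 4, length(keepOff)),
                  dimnames = list(anc = NUC, desc = NUC, offset = offs[keepOff]))
  ambiguous <- integer(length(keepOff))
  excluded <- integer(length(keepOff))
  for (jj in seq_along(keepOff)) {
    j <- keepOff[jj]
    a <- anc[, j]
    amb <- is.na(a)
    exc <- !amb & cpg[, j]
    use <- !amb & !exc
    ambiguous[jj] <- sum(amb)
    excluded[jj] <- sum(exc)
    if (any(use)) {
      tab <- table(factor(a[use], levels = 1:4),
                   factor(sq$ref[use, j], levels = 1:4))
      counts[, , jj] <- counts[, , jj] + as.integer(tab)
    }
  }
  new("SubstitutionCounts", siteType = st, offsets = offs[keepOff],
      counts = counts, ambiguous = ambiguous, excluded = excluded,
      nRecords = n)
}

#' Tabulate control-position substitutions by ancestral nucleotide
#'
#' Applies the neutrality-score filter, reconstructs ancestors by maximum
#' parsimony and counts ancestral -> descendant events pooled over the
#' retained control positions.
#'
#' @param controls list of [ControlColumns-class] objects (or a single one).
#' @param threshold neutrality-score threshold (default 0.6).
#' @param keepBelow retain positions with |score| < threshold (the default);
#'   `FALSE` selects the complementary reading (|score| >= threshold).
#' @return a [NeutralRates-class].
#' @export
neutralRates <- function(controls, threshold = 0.6, keepBelow = TRUE) {
  if (is(controls, "ControlColumns")) controls <- list(controls)
  counts <- list()
  nFiltered <- integer(0)
  for (ctl in controls) {
    keep <- if (keepBelow) abs(ctl@score) < threshold
            else abs(ctl@score) >= threshold
    nFiltered[[ctl@provenance]] <- sum(!keep)
    if (!any(keep))
      stop("no control positions pass the score filter (", ctl@provenance, ")")
    a <- match(parsimonyAncestor(ctl@ref[keep], ctl@sister[keep],
                                 ctl@outgroup[keep]), NUC)
    ok <- !is.na(a)
    tab <- table(factor(a[ok], levels = 1:4),
                 factor(ctl@ref[keep][ok], levels = 1:4))
    m <- matrix(as.integer(tab), 4, 4, dimnames = list(anc = NUC, desc = NUC))
    counts[[ctl@provenance]] <- m
  }
  new("NeutralRates", counts = counts, nFiltered = nFiltered,
      threshold = threshold, keepBelow = keepBelow)
}

#' Neutral substitution rate from an ancestral nucleotide to a target set
#'
#' r_Z(T) = #(Z -> T) / #(Z -> anything), from the filtered control counts of
#' the requested provenance. Rates are additive over disjoint target sets.
#'
#' @param neutral a [NeutralRates-class].
#' @param provenance "intronic" or "fourfold".
#' @param from ancestral nucleotide (A/C/G/T).
#' @param target character vector of target nucleotides (excluding `from`).
#' @return list with `k`, `n`, `rate`.
#' @export
neutralRate <- function(neutral, provenance, from, target) {
  m <- neutral@counts[[provenance]]
  if (is.null(m)) stop("no ", provenance, " controls available")
  if (from %in% target) stop("target set must not contain the source allele")
  k <- sum(m[from, target])
  n <- sum(m[from, ])
  if (n == 0) stop("no control positions with ancestral ", from)
  list(k = k, n = n, rate = k / n)
}
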
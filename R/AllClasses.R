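#' @import methods
#' @importFrom stats quantile rbinom rnorm runif qbeta uniroot fisher.test
#'   p.adjust setNames sd
#' @importFrom utils read.delim write.table packageVersion head
NULL

NUC <- c("A", "C", "G", "T")

#' ConsensusTable: consensus nucleotides and position roles along a splice site
#'
#' Holds, for each (site type, offset), the set of one or two consensus (Cn)
#' nucleotides and the role of the position: `exonic` or `intronic` positions
#' are scored, `invariant` marks the canonical GT/AG dinucleotide, and
#' `no_consensus` marks positions where no Cn can be established.
#'
#' Offsets follow the signed convention with no zero: donor sites span -3..-1
#' (exonic) and +1..+6 (intronic, GT at +1,+2); acceptor sites span -24..-1
#' (intronic, AG at -2,-1) and +1 (exonic).
#'
#' @slot table data.frame with columns `siteType`, `offset`, `role`, `cn`
#'   (consensus nucleotides concatenated, e.g. `"TC"`; `""` for invariant and
#'   no-consensus positions).
#' @seealso [defaultConsensus()], [deriveConsensus()], [cnSet()],
#'   [positionRole()]
#' @export
setClass("ConsensusTable", representation(table = "data.frame"))

setValidity("ConsensusTable", function(object) {
  tab <- object@table
  need <- c("siteType", "offset", "role", "cn")
  if (!all(need %in% names(tab)))
    return(sprintf("table must have columns %s", paste(need, collapse = ", ")))
  if (!all(tab$siteType %in% c("donor", "acceptor")))
    return("siteType must be 'donor' or 'acceptor'")
  if (any(tab$offset == 0)) return("offset 0 does not exist")
  bad <- tab$role %in% c("exonic", "intronic") & !nchar(tab$cn) %in% c(1L, 2L)
  if (any(bad)) return("scored positions must carry 1 or 2 Cn nucleotides")
  # canonical dinucleotide roles are fixed by the site architecture
  inv <- tab[tab$role == "invariant", ]
  key <- paste(inv$siteType, inv$offset)
  want <- c("donor 1", "donor 2", "acceptor -2", "acceptor -1")
  if (any(tab$siteType == "donor") && !all(c("donor 1", "donor 2") %in% key))
    return("donor +1/+2 must be invariant")
  if (any(tab$siteType == "acceptor") &&
      !all(c("acceptor -2", "acceptor -1") %in% key))
    return("acceptor -2/-1 must be invariant")
  if (!all(key %in% want)) return("invariant role only at the canonical GT/AG")
  TRUE
})

#' SpliceSiteEnsemble: aligned splice-site triplets for one site type
#'
#' Container for an ensemble of donor or acceptor splice sites with aligned
#' reference, sister and outgroup sequences over the site's offset range,
#' per-site annotation labels, and (for simulated data) the ground-truth
#' selection coefficients used to generate each column.
#'
#' Sequences are stored as integer matrices (1..4 = A,C,G,T; NA = missing)
#' with one row per site and one column per offset.
#'
#' @slot siteType "donor" or "acceptor".
#' @slot offsets integer vector of signed offsets (no zero), one per column.
#' @slot seqs named list of integer matrices `ref`, `sister`, `outgroup`.
#' @slot info data.frame of per-site labels (siteId, codingClass,
#'   splicingClass, and optionally strengthFraction/strengthClass).
#' @slot truth list with ground truth from simulation: `S` (numeric matrix of
#'   the 4Nes applying to a Cn-to-Nc change at each site x offset) and
#'   `favored` (integer matrix, the site-specifically favored Nc allele or
#'   NA); empty list for real data.
#' @export
setClass("SpliceSiteEnsemble",
  representation(siteType = "character", offsets = "integer",
                 seqs = "list", info = "data.frame", truth = "list"))

setValidity("SpliceSiteEnsemble", function(object) {
  if (!object@siteType %in% c("donor", "acceptor"))
    return("siteType must be 'donor' or 'acceptor'")
  if (any(object@offsets == 0L)) return("offset 0 does not exist")
  sp <- c("ref", "sister", "outgroup")
  if (!all(sp %in% names(object@seqs)))
    return("seqs must contain ref, sister, outgroup")
  dims <- vapply(object@seqs[sp], dim, integer(2))
  if (length(unique(dims[2, ])) != 1L ||
      dims[2, 1] != length(object@offsets))
    return("sequence matrices must have one column per offset")
  if (length(unique(dims[1, ])) != 1L)
    return("sequence matrices must agree in site count")
  if (nrow(object@info) != dims[1, 1])
    return("info must have one row per site")
  TRUE
})

#' ControlColumns: matched neutral control positions
#'
#' Neutral control columns (reference/sister/outgroup states) with per-position
#' neutrality scores (phyloP-like) and a provenance label saying whether the
#' controls stand in for intronic sequence or for third positions of 4-fold
#' degenerate codons.
#'
#' @slot provenance "intronic" or "fourfold".
#' @slot ref,sister,outgroup integer vectors (1..4 = A,C,G,T).
#' @slot score numeric neutrality scores.
#' @export
setClass("ControlColumns",
  representation(provenance = "character", ref = "integer",
                 sister = "integer", outgroup = "integer", score = "numeric"))

setValidity("ControlColumns", function(object) {
  if (!object@provenance %in% c("intronic", "fourfold"))
    return("provenance must be 'intronic' or 'fourfold'")
  n <- length(object@ref)
  if (length(object@sister) != n || length(object@outgroup) != n ||
      length(object@score) != n)
    return("ref, sister, outgroup, score must have equal length")
  TRUE
})

#' SubstitutionCounts: ancestral-to-descendant substitution tallies
#'
#' Per offset, the 4x4 matrix `#(Z->X)` of counts of columns whose
#' parsimony-reconstructed ancestor is Z and whose reference-lineage descendant
#' is X (diagonal = conserved columns), plus tallies of columns dropped as
#' ambiguous or excluded (CpG filter).
#'
#' @slot siteType "donor" or "acceptor".
#' @slot offsets integer offsets of the counted (non-invariant) positions.
#' @slot counts 4 x 4 x length(offsets) integer array, dims anc x desc x offset.
#' @slot ambiguous,excluded integer vectors per offset.
#' @slot nRecords total number of records counted against.
#' @export
setClass("SubstitutionCounts",
  representation(siteType = "character", offsets = "integer",
                 counts = "array", ambiguous = "integer",
                 excluded = "integer", nRecords = "integer"))

setValidity("SubstitutionCounts", function(object) {
  d <- dim(object@counts)
  if (length(d) != 3L || d[1] != 4L || d[2] != 4L ||
      d[3] != length(object@offsets))
    return("counts must be a 4 x 4 x n_offsets array")
  if (any(object@counts < 0)) return("counts must be non-negative")
  tot <- apply(object@counts, 3, sum) + object@ambiguous + object@excluded
  if (any(tot > object@nRecords))
    return("per-offset totals exceed the number of records")
  TRUE
})

#' NeutralRates: nucleotide-matched neutral substitution rates
#'
#' Substitution counts from neutral control positions that passed the
#' neutrality-score filter, keyed by ancestral nucleotide, one 4x4 matrix per
#' provenance. Rates to any target set are derived on demand with
#' [neutralRate()].
#'
#' @slot counts named list of 4x4 matrices (`intronic`, `fourfold`), dims
#'   anc x desc.
#' @slot nFiltered named integer: control positions removed by the score
#'   filter per provenance.
#' @slot threshold numeric neutrality-score threshold.
#' @slot keepBelow logical; TRUE retains positions with |score| < threshold.
#' @export
setClass("NeutralRates",
  representation(counts = "list", nFiltered = "integer",
                 threshold = "numeric", keepBelow = "logical"))

#' PanelEnsemble: multispecies alignment columns on a distance ladder
#'
#' Extant states for the reference species plus a panel of species ordered by
#' increasing phylogenetic distance (Ks units) from the reference, for every
#' site x offset of a splice-site ensemble, or for matched neutral control
#' columns (offset NA).
#'
#' @slot siteType "donor", "acceptor" or "control".
#' @slot offsets integer offsets (length 1, NA, for controls).
#' @slot distances numeric non-decreasing Ks distances, one per panel species.
#' @slot ref integer matrix site x offset of reference states.
#' @slot species integer array site x offset x panel-species.
#' @export
setClass("PanelEnsemble",
  representation(siteType = "character", offsets = "integer",
                 distances = "numeric", ref = "matrix", species = "array"))

setValidity("PanelEnsemble", function(object) {
  if (is.unsorted(object@distances))
    return("distances must be non-decreasing")
  d <- dim(object@species)
  if (length(d) != 3L || d[3] != length(object@distances))
    return("species array must have one slice per panel species")
  if (!all(d[1:2] == dim(object@ref)))
    return("ref and species dimensions disagree")
  TRUE
})

setMethod("show", "ConsensusTable", function(object) {
  tab <- object@table
  for (st in unique(tab$siteType)) {
    sub <- tab[tab$siteType == st, ]
    sc <- sum(sub$role %in% c("exonic", "intronic"))
    cat(sprintf("%s: offsets %+d..%+d, %d scored positions\n",
                st, min(sub$offset), max(sub$offset), sc))
  }
  invisible(NULL)
})

setMethod("show", "SpliceSiteEnsemble", function(object) {
  cat(sprintf("SpliceSiteEnsemble: %d %s sites, offsets %+d..%+d%s\n",
              nrow(object@info), object@siteType, min(object@offsets),
              max(object@offsets),
              if (length(object@truth)) " (simulated, truth attached)" else ""))
  invisible(NULL)
})

setMethod("show", "SubstitutionCounts", function(object) {
  cat(sprintf(
    "SubstitutionCounts: %s, %d offsets, %d records (%d ambiguous, %d excluded column events)\n",
    object@siteType, length(object@offsets), object@nRecords,
    sum(object@ambiguous), sum(object@excluded)))
  invisible(NULL)
})

setMethod("show", "ControlColumns", function(object) {
  cat(sprintf("ControlColumns: %d %s control positions\n",
              length(object@ref), object@provenance))
  invisible(NULL)
})

setMethod("show", "NeutralRates", function(object) {
  for (pv in names(object@counts))
    cat(sprintf("NeutralRates[%s]: n = %d (filtered out %d), |score| %s %g\n",
                pv, sum(object@counts[[pv]]), object@nFiltered[[pv]],
                if (object@keepBelow) "<" else ">=", object@threshold))
  invisible(NULL)
})

setMethod("show", "PanelEnsemble", function(object) {
  cat(sprintf("PanelEnsemble: %s, %d x %d columns, %d panel species to Ks %.2f\n",
              object@siteType, nrow(object@ref), ncol(object@ref),
              length(object@distances), max(object@distances)))
  invisible(NULL)
})

## ---- accessors ----

#' Accessors for spliceDrift containers
#'
#' @param x a spliceDrift S4 object.
#' @param ... passed on to methods.
#' @return `siteType` the site type; `offsets` the signed offset vector;
#'   `siteInfo` the per-site annotation data.frame; `siteSeqs` the named list
#'   of integer sequence matrices; `groundTruth` the simulation truth list.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("siteType", function(x, ...) standardGeneric("siteType"))
#' @rdname accessors
#' @export
setGeneric("offsets", function(x, ...) standardGeneric("offsets"))
#' @rdname accessors
#' @export
setGeneric("siteInfo", function(x, ...) standardGeneric("siteInfo"))
#' @rdname accessors
#' @export
setGeneric("siteSeqs", function(x, ...) standardGeneric("siteSeqs"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x, ...) standardGeneric("groundTruth"))

#' @rdname accessors
setMethod("siteType", "SpliceSiteEnsemble", function(x, ...) x@siteType)
#' @rdname accessors
setMethod("siteType", "SubstitutionCounts", function(x, ...) x@siteType)
#' @rdname accessors
setMethod("siteType", "PanelEnsemble", function(x, ...) x@siteType)
#' @rdname accessors
setMethod("offsets", "SpliceSiteEnsemble", function(x, ...) x@offsets)
#' @rdname accessors
setMethod("offsets", "SubstitutionCounts", function(x, ...) x@offsets)
#' @rdname accessors
setMethod("siteInfo", "SpliceSiteEnsemble", function(x, ...) x@info)
#' @rdname accessors
setMethod("siteSeqs", "SpliceSiteEnsemble", function(x, ...) x@seqs)
#' @rdname accessors
setMethod("groundTruth", "SpliceSiteEnsemble", function(x, ...) x@truth)

#' Substitution count matrix at one offset
#'
#' @param x a [SubstitutionCounts-class] object.
#' @param offset signed offset.
#' @return 4x4 integer matrix, rows = ancestral, columns = descendant.
#' @export
countMatrix <- function(x, offset) {
  stopifnot(is(x, "SubstitutionCounts"))
  i <- match(offset, x@offsets)
  if (is.na(i)) stop("offset ", offset, " not tabulated")
  m <- x@counts[, , i]
  dimnames(m) <- list(anc = NUC, desc = NUC)
  m
}
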
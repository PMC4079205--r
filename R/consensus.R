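## Site architecture: fixed offset ranges and roles.

donorOffsets <- function() c(-3:-1, 1:6)
acceptorOffsets <- function() c(-24:-1, 1)

siteOffsets <- function(siteType) {
  switch(siteType, donor = donorOffsets(), acceptor = acceptorOffsets(),
         stop("unknown site type: ", siteType))
}

roleOf <- function(siteType, offset) {
  if (siteType == "donor") {
    if (offset %in% c(1L, 2L)) "invariant"
    else if (offset < 0L) "exonic"
    else "intronic"
  } else {
    if (offset %in% c(-2L, -1L)) "invariant"
    else if (offset == -4L) "no_consensus"
    else if (offset < 0L) "intronic"
    else "exonic"
  }
}

#' Role of a splice-site position
#'
#' Deterministic lookup of the role of an offset within the donor or acceptor
#' site architecture: `exonic` and `intronic` positions are scored for
#' consensus, `invariant` marks the canonical GT (donor +1,+2) / AG (acceptor
#' -2,-1) dinucleotide, and `no_consensus` marks acceptor -4, where no
#' consensus nucleotide can be established.
#'
#' @param siteType "donor" or "acceptor".
#' @param offset signed offset (donor -3..+6, acceptor -24..+1; no zero).
#' @return character role.
#' @examples
#' positionRole("donor", -1)     # exonic
#' positionRole("acceptor", -2)  # invariant
#' positionRole("acceptor", 1)   # exonic
#' @export
positionRole <- function(siteType, offset) {
  siteType <- match.arg(siteType, c("donor", "acceptor"))
  if (length(offset) != 1L || !offset %in% siteOffsets(siteType))
    stop("offset ", offset, " outside the ", siteType, " range")
  roleOf(siteType, as.integer(offset))
}

invariantBase <- function(siteType, offset) {
  # canonical GT / AG
  if (siteType == "donor") c(`1` = "G", `2` = "T")[[as.character(offset)]]
  else c(`-2` = "A", `-1` = "G")[[as.character(offset)]]
}

newConsensusTable <- function(tab) {
  tab$offset <- as.integer(tab$offset)
  rownames(tab) <- NULL
  new("ConsensusTable", table = tab[order(tab$siteType, tab$offset), ])
}

#' Default splice-site consensus table
#'
#' Ships the canonical U2-type GT-AG consensus used when no frequency table is
#' supplied: donor (C/A)AG | GTRAGT and acceptor polypyrimidine tract followed
#' by NCAG | G. This table is configuration, not data-derived ground truth;
#' tables computed from an ensemble with [deriveConsensus()] override it.
#'
#' @return a [ConsensusTable-class].
#' @export
defaultConsensus <- function() {
  cn <- list(
    donor = c(`-3` = "CA", `-2` = "A", `-1` = "G",
              `3` = "AG", `4` = "A", `5` = "G", `6` = "T"),
    acceptor = c(`-3` = "C", `1` = "G"))
  # polypyrimidine tract: -24..-5 favor T/C
  for (o in -24:-5) cn$acceptor[[as.character(o)]] <- "TC"
  rows <- do.call(rbind, lapply(c("donor", "acceptor"), function(st) {
    offs <- siteOffsets(st)
    data.frame(siteType = st, offset = offs,
               role = vapply(offs, function(o) roleOf(st, o), ""),
               cn = vapply(offs, function(o) {
                 r <- roleOf(st, o)
                 if (r %in% c("invariant", "no_consensus")) ""
                 else cn[[st]][[as.character(o)]]
               }, ""))
  }))
  newConsensusTable(rows)
}

#' Derive a consensus table from per-position nucleotide frequencies
#'
#' At every scored position the most frequent nucleotide is always consensus
#' (Cn); the second most frequent is included iff its frequency reaches
#' `secondaryThreshold`, so each Cn set has size one or two. Invariant and
#' no-consensus roles are forced by the site architecture regardless of the
#' supplied frequencies. Frequencies need not be normalized; the result is
#' invariant to rescaling.
#'
#' @param freqs named list with elements `donor` and/or `acceptor`, each a
#'   numeric matrix with one row per offset (rownames = signed offsets) and
#'   columns A,C,G,T. Alternatively a [SpliceSiteEnsemble-class], in which
#'   case reference-sequence frequencies are tabulated first.
#' @param secondaryThreshold minimum relative frequency for a second Cn
#'   nucleotide (default 0.35).
#' @return a [ConsensusTable-class].
#' @export
deriveConsensus <- function(freqs, secondaryThreshold = 0.35) {
  if (is(freqs, "SpliceSiteEnsemble")) {
    m <- freqs@seqs$ref
    fm <- t(apply(m, 2, function(col) tabulate(col, 4L)))
    rownames(fm) <- freqs@offsets
    colnames(fm) <- NUC
    freqs <- setNames(list(fm), freqs@siteType)
  }
  rows <- do.call(rbind, lapply(names(freqs), function(st) {
    fm <- freqs[[st]]
    offs <- as.integer(rownames(fm))
    cn <- vapply(seq_along(offs), function(i) {
      r <- roleOf(st, offs[i])
      if (r %in% c("invariant", "no_consensus")) return("")
      f <- fm[i, NUC]
      f <- f / sum(f)
      ord <- order(-f, NUC)  # ties resolved alphabetically
      top <- NUC[ord[1]]
      second <- NUC[ord[2]]
      if (f[ord[2]] >= secondaryThreshold) {
        if (abs(f[ord[2]] - secondaryThreshold) < .Machine$double.eps^0.5 &&
            length(ord) > 2 && abs(f[ord[3]] - f[ord[2]]) < .Machine$double.eps^0.5)
          message("tie at the secondary threshold for ", st, " offset ",
                  offs[i], "; resolved alphabetically")
        paste0(top, second)
      } else top
    }, "")
    data.frame(siteType = st, offset = offs,
               role = vapply(offs, function(o) roleOf(st, o), ""), cn = cn)
  }))
  # positions absent from the frequency table keep architecture roles only if
  # the full offset range was provided; require completeness
  for (st in names(freqs)) {
    missing <- setdiff(siteOffsets(st), rows$offset[rows$siteType == st])
    if (length(missing))
      stop("frequency table for ", st, " lacks offsets ",
           paste(missing, collapse = ", "))
  }
  newConsensusTable(rows)
}

#' Consensus nucleotides at a position
#'
#' @param consensus a [ConsensusTable-class].
#' @param siteType "donor" or "acceptor".
#' @param offset signed offset.
#' @return character vector of 1 or 2 Cn nucleotides; `character(0)` for
#'   invariant and no-consensus positions.
#' @export
cnSet <- function(consensus, siteType, offset) {
  tab <- consensus@table
  i <- which(tab$siteType == siteType & tab$offset == offset)
  if (!length(i)) stop("no entry for ", siteType, " offset ", offset)
  strsplit(tab$cn[i], "")[[1]]
}

#' Scored offsets of a site type
#'
#' Offsets with role exonic or intronic and a defined Cn set (donor: 7;
#' acceptor: 23).
#'
#' @inheritParams cnSet
#' @return integer vector of offsets.
#' @export
scoredOffsets <- function(consensus, siteType) {
  tab <- consensus@table
  sub <- tab[tab$siteType == siteType &
             tab$role %in% c("exonic", "intronic") & nchar(tab$cn) > 0, ]
  sort(sub$offset)
}
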
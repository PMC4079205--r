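## Origination-fixation (weak-mutation) sequence-evolution simulator.
##
## Substitutions, not populations, are simulated: the rate of the Z -> X
## substitution is mu(Z->X) * r(S_X - S_Z), where r is the Kimura
## fixation-rate ratio and S are population-scaled fitnesses (4Nes scale).

#' Kappa-parameterized neutral mutation-rate matrix
#'
#' Symmetric mutation matrix with a single transition/transversion ratio
#' kappa, normalized so that one Ks unit corresponds to one expected neutral
#' substitution per site (rows/cols in A,C,G,T order; diagonal zero).
#'
#' @param kappa transition/transversion rate ratio (default 2).
#' @return 4x4 numeric matrix of per-Ks mutation rates.
#' @export
mutationMatrixKappa <- function(kappa = 2) {
  stopifnot(kappa > 0)
  m <- matrix(1, 4, 4, dimnames = list(NUC, NUC))
  diag(m) <- 0
  m["A", "G"] <- m["G", "A"] <- m["C", "T"] <- m["T", "C"] <- kappa
  normalizeMutationMatrix(m)
}

## scales rates so the neutral expected substitutions per Ks unit equal 1
normalizeMutationMatrix <- function(m) {
  diag(m) <- 0
  if (any(m < 0)) stop("mutation rates must be non-negative")
  pi0 <- stationaryFrequencies(m, rep(0, nrow(m)))
  m / sum(pi0 * rowSums(m))
}

rateMatrix <- function(mutationMatrix, selection) {
  k <- nrow(mutationMatrix)
  stopifnot(length(selection) == k, all(is.finite(selection)))
  Q <- mutationMatrix * fixationRatio(outer(selection, selection,
                                            function(z, x) x - z))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary allele frequencies of the substitution process
#'
#' Equilibrium frequencies of the mutation-selection-drift origination-fixation
#' process whose Z -> X rate is mu(Z->X) * r(S_X - S_Z). For a symmetric
#' mutation matrix the process is reversible with pi_X proportional to
#' exp(S_X) (detailed balance); for general mutation matrices the stationary
#' vector is solved from the rate matrix.
#'
#' @param mutationMatrix square non-negative rate matrix (diagonal ignored).
#' @param selection numeric fitness vector on the 4Nes scale, one per allele.
#' @return numeric frequency vector summing to 1.
#' @export
stationaryFrequencies <- function(mutationMatrix, selection) {
  k <- nrow(mutationMatrix)
  A <- mutationMatrix
  diag(A) <- 0
  if (any(A < 0)) stop("mutation rates must be non-negative")
  # require the allele graph to be strongly connected
  reach <- (diag(k) + (A > 0)) %*% diag(k)
  for (i in seq_len(k)) reach <- reach %*% (diag(k) + (A > 0))
  if (any(reach == 0))
    stop("mutation matrix is absorbing or disconnected; no unique stationary state")
  Q <- rateMatrix(mutationMatrix, selection)
  sol <- qr.solve(rbind(t(Q), rep(1, k)), c(rep(0, k), 1))
  sol <- pmax(sol, 0)
  sol / sum(sol)
}

#' Branch transition probabilities of the substitution process
#'
#' Matrix exponential of the selection-weighted substitution-rate matrix over
#' a branch of the given length (Ks units).
#'
#' @param branchLength branch length in Ks units (>= 0).
#' @inheritParams stationaryFrequencies
#' @return square stochastic matrix of transition probabilities.
#' @export
substitutionMatrix <- function(branchLength, mutationMatrix, selection) {
  if (!is.finite(branchLength) || branchLength < 0)
    stop("branch length must be >= 0")
  k <- nrow(mutationMatrix)
  if (branchLength == 0) return(diag(k))
  Q <- rateMatrix(mutationMatrix, selection)
  P <- as.matrix(Matrix::expm(Q * branchLength))
  P <- pmax(P, 0)
  P / rowSums(P)
}

#' Simulation parameters for the splice-site substitution simulator
#'
#' Bundles and validates everything the generator needs. Defaults emulate the
#' primate triplet design: reference and sister branches of 0.03 Ks each
#' since their divergence, an inner branch of 0.01 Ks and an outgroup branch
#' of 0.06 Ks from the root, kappa = 2 mutation, and a 12-species panel
#' ladder reaching Ks = 4.
#'
#' `S` is the 4Nes that applies to a Cn -> Nc change (negative values mean
#' the consensus is favored); it may be a single number applied to every
#' scored offset or a named vector keyed by offset. A fraction
#' `siteSpecificFraction` of sites instead favors, at each scored offset, one
#' uniformly chosen Nc allele with advantage `siteSpecificS` (4Nes) over all
#' other alleles.
#'
#' @param nSites number of splice sites to simulate.
#' @param siteType "donor" or "acceptor".
#' @param S 4Nes of a Cn->Nc change (scalar or named by offset). Default 0.
#' @param consensus a [ConsensusTable-class] (default [defaultConsensus()]).
#' @param siteSpecificFraction fraction of sites with a site-specifically
#'   favored Nc allele (default 0).
#' @param siteSpecificS 4Nes advantage of the favored Nc allele (default 2).
#' @param mutationMatrix 4x4 per-Ks mutation rates; renormalized so one Ks
#'   unit = one expected neutral substitution.
#' @param ksRef,ksSister branch lengths from the reference/sister common
#'   ancestor to each extant species (Ks).
#' @param ksInner branch length root -> (ref, sister) ancestor.
#' @param ksOutgroup branch length root -> outgroup.
#' @param panelDistances non-decreasing Ks distances of the multispecies
#'   panel ladder.
#' @param controlFactor neutral control columns generated per observed scored
#'   column, per provenance (default 10).
#' @param codingFraction fraction of sites labeled "coding" (default 0.8).
#' @param cpgRateMultiplier mutation-rate multiplier applied to columns in
#'   ancestral CpG context (default 1: a CpG flag is annotated but no rate
#'   mechanism is active).
#' @param seed integer master seed (mandatory).
#' @return a list of class "SimParams".
#' @export
simParams <- function(nSites, siteType = c("donor", "acceptor"), S = 0,
                      consensus = defaultConsensus(),
                      siteSpecificFraction = 0, siteSpecificS = 2,
                      mutationMatrix = mutationMatrixKappa(2),
                      ksRef = 0.03, ksSister = 0.03, ksInner = 0.01,
                      ksOutgroup = 0.06,
                      panelDistances = c(0.05, 0.1, 0.2, 0.35, 0.55, 0.8,
                                         1.1, 1.5, 2.0, 2.6, 3.3, 4.0),
                      controlFactor = 10, codingFraction = 0.8,
                      cpgRateMultiplier = 1, seed) {
  siteType <- match.arg(siteType)
  if (missing(seed) || !is.finite(seed)) stop("an integer seed is mandatory")
  stopifnot(nSites >= 1, siteSpecificFraction >= 0, siteSpecificFraction <= 1,
            ksRef >= 0, ksSister >= 0, ksInner >= 0, ksOutgroup >= 0,
            all(panelDistances >= 0), !is.unsorted(panelDistances),
            controlFactor > 0, cpgRateMultiplier > 0)
  mutationMatrix <- normalizeMutationMatrix(mutationMatrix)
  offs <- siteOffsets(siteType)
  scored <- scoredOffsets(consensus, siteType)
  if (is.null(names(S))) {
    stopifnot(length(S) == 1)
    S <- setNames(rep(S, length(scored)), scored)
  } else {
    miss <- setdiff(as.character(scored), names(S))
    if (length(miss)) stop("S lacks offsets ", paste(miss, collapse = ", "))
    S <- S[as.character(scored)]
  }
  structure(list(nSites = as.integer(nSites), siteType = siteType, S = S,
                 consensus = consensus,
                 siteSpecificFraction = siteSpecificFraction,
                 siteSpecificS = siteSpecificS,
                 mutationMatrix = mutationMatrix, ksRef = ksRef,
                 ksSister = ksSister, ksInner = ksInner,
                 ksOutgroup = ksOutgroup, panelDistances = panelDistances,
                 controlFactor = controlFactor,
                 codingFraction = codingFraction,
                 cpgRateMultiplier = cpgRateMultiplier,
                 seed = as.integer(seed), offsets = offs),
            class = "SimParams")
}

## one vectorized transition draw: child states given parent states and P
evolveStates <- function(parent, P) {
  cumP <- t(apply(P, 1, cumsum))
  u <- runif(length(parent))
  child <- rep.int(1L, length(parent))
  for (k in seq_len(ncol(P) - 1L))
    child <- child + (u > cumP[cbind(parent, k)])
  child
}

## fitness vector (4Nes scale) for one offset: 0 for Cn, S for Nc
offsetFitness <- function(consensus, siteType, offset, S) {
  role <- roleOf(siteType, offset)
  f <- rep(0, 4)
  if (role %in% c("exonic", "intronic")) {
    cn <- match(cnSet(consensus, siteType, offset), NUC)
    f[setdiff(1:4, cn)] <- S
  }
  f
}

#' Simulate triplet columns under one fitness regime
#'
#' Low-level generator: draws `n` independent columns with the root at the
#' stationary state of the process and descendants evolved along the
#' ((ref, sister), outgroup) topology. Uses the current RNG state.
#'
#' @param n number of columns.
#' @param mutationMatrix 4x4 per-Ks mutation rates.
#' @param fitness numeric length-4 fitness vector (4Nes scale).
#' @param ksRef,ksSister,ksInner,ksOutgroup branch lengths (Ks).
#' @return list of integer vectors `root`, `anc`, `ref`, `sister`, `outgroup`.
#' @export
simulateColumns <- function(n, mutationMatrix, fitness, ksRef, ksSister,
                            ksInner, ksOutgroup) {
  pi0 <- stationaryFrequencies(mutationMatrix, fitness)
  root <- sample.int(4L, n, replace = TRUE, prob = pi0)
  anc <- evolveStates(root, substitutionMatrix(ksInner, mutationMatrix, fitness))
  list(root = root, anc = anc,
       ref = evolveStates(anc, substitutionMatrix(ksRef, mutationMatrix, fitness)),
       sister = evolveStates(anc, substitutionMatrix(ksSister, mutationMatrix, fitness)),
       outgroup = evolveStates(root, substitutionMatrix(ksOutgroup, mutationMatrix, fitness)))
}

#' Simulate a splice-site triplet ensemble
#'
#' Generates `params$nSites` splice sites of the requested type with aligned
#' reference, sister and outgroup sequences. Each non-invariant column evolves
#' under the origination-fixation process with the offset's fitness vector;
#' the canonical GT/AG positions are hard-coded immutable, so every record
#' carries the canonical dinucleotides in all species. Ground-truth selection
#' coefficients (and site-specifically favored alleles, where drawn) are
#' attached. Deterministic for a fixed `params$seed`.
#'
#' @param params a [simParams()] object.
#' @return a [SpliceSiteEnsemble-class].
#' @export
simulateTripletEnsemble <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  set.seed(params$seed)
  n <- params$nSites
  st <- params$siteType
  offs <- params$offsets
  K <- length(offs)
  mk <- function() matrix(NA_integer_, n, K, dimnames = list(NULL, offs))
  ref <- mk(); sister <- mk(); outgroup <- mk(); rootm <- mk()
  trueS <- matrix(NA_real_, n, K, dimnames = list(NULL, offs))
  favored <- matrix(NA_integer_, n, K, dimnames = list(NULL, offs))

  ssIdx <- integer(0)
  if (params$siteSpecificFraction > 0)
    ssIdx <- sort(sample.int(n, round(params$siteSpecificFraction * n)))

  for (j in seq_len(K)) {
    o <- offs[j]
    role <- roleOf(st, o)
    if (role == "invariant") {
      b <- match(invariantBase(st, o), NUC)
      ref[, j] <- sister[, j] <- outgroup[, j] <- rootm[, j] <- b
      next
    }
    Sj <- if (role == "no_consensus") 0 else params$S[[as.character(o)]]
    trueS[, j] <- Sj
    f0 <- offsetFitness(params$consensus, st, o, Sj)
    plain <- setdiff(seq_len(n), if (role == "no_consensus") integer(0) else ssIdx)
    groups <- list(list(idx = plain, fitness = f0))
    if (length(ssIdx) && role != "no_consensus") {
      nc <- setdiff(1:4, match(cnSet(params$consensus, st, o), NUC))
      fav <- nc[sample.int(length(nc), length(ssIdx), replace = TRUE)]
      favored[ssIdx, j] <- fav
      for (a in unique(fav)) {
        fa <- f0
        fa[a] <- params$siteSpecificS
        groups <- c(groups, list(list(idx = ssIdx[fav == a], fitness = fa)))
      }
    }
    for (g in groups) {
      if (!length(g$idx)) next
      cols <- simulateColumns(length(g$idx), params$mutationMatrix, g$fitness,
                              params$ksRef, params$ksSister, params$ksInner,
                              params$ksOutgroup)
      rootm[g$idx, j] <- cols$root
      ref[g$idx, j] <- cols$ref
      sister[g$idx, j] <- cols$sister
      outgroup[g$idx, j] <- cols$outgroup
    }
  }

  # optional CpG hypermutability: columns in root-sequence CpG context are
  # re-evolved from the same root with uniformly scaled rates
  if (params$cpgRateMultiplier != 1) {
    flag <- cpgContext(rootm)
    for (j in seq_len(K)) {
      o <- offs[j]
      role <- roleOf(st, o)
      if (role == "invariant") next
      idx <- which(flag[, j])
      if (!length(idx)) next
      Sj <- if (role == "no_consensus") 0 else params$S[[as.character(o)]]
      f0 <- offsetFitness(params$consensus, st, o, Sj)
      mu2 <- params$mutationMatrix * params$cpgRateMultiplier
      anc <- evolveStates(rootm[idx, j],
                          substitutionMatrix(params$ksInner, mu2, f0))
      ref[idx, j] <- evolveStates(anc, substitutionMatrix(params$ksRef, mu2, f0))
      sister[idx, j] <- evolveStates(anc, substitutionMatrix(params$ksSister, mu2, f0))
      outgroup[idx, j] <- evolveStates(rootm[idx, j],
                                       substitutionMatrix(params$ksOutgroup, mu2, f0))
    }
  }

  info <- data.frame(
    siteId = sprintf("%s%06d", substr(st, 1, 3), seq_len(n)),
    codingClass = ifelse(runif(n) < params$codingFraction, "coding", "noncoding"),
    splicingClass = "constitutive")
  new("SpliceSiteEnsemble", siteType = st, offsets = as.integer(offs),
      seqs = list(ref = ref, sister = sister, outgroup = outgroup),
      info = info, truth = list(S = trueS, favored = favored))
}

## TRUE where a position is part of a CG dinucleotide in its sequence context.
## With naAsWild, an ambiguous (NA) neighbour counts as a possible CpG partner
## (conservative exclusion on reconstructed ancestors).
cpgContext <- function(m, naAsWild = FALSE) {
  K <- ncol(m)
  isC <- m == 2L & !is.na(m)
  isG <- m == 3L & !is.na(m)
  nG <- isG
  pC <- isC
  if (naAsWild) {
    nG <- nG | is.na(m)
    pC <- pC | is.na(m)
  }
  nextG <- cbind(nG[, -1, drop = FALSE], FALSE)
  prevC <- cbind(FALSE, pC[, -K, drop = FALSE])
  (isC & nextG) | (isG & prevC)
}

#' Simulate matched neutral control columns
#'
#' Generates neutral (S = 0) triplet columns under the same mutation process
#' and branch lengths as the splice-site ensemble, for both control
#' provenances (intronic sequence and third positions of 4-fold degenerate
#' codons). The number of columns per provenance is `controlFactor` times the
#' ensemble's scored columns of that provenance. Each column carries a
#' phyloP-like neutrality score drawn from the mixture
#' 0.5 N(0, 0.3) + 0.5 N(0, 1.2), so that roughly half the positions are
#' removed by the default |score| < 0.6 retention filter. Deterministic for a
#' fixed `params$seed`.
#'
#' @param params a [simParams()] object.
#' @return named list of two [ControlColumns-class] objects
#'   (`intronic`, `fourfold`).
#' @export
simulateControls <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  set.seed(params$seed + 1L)
  scored <- scoredOffsets(params$consensus, params$siteType)
  roles <- vapply(scored, function(o) roleOf(params$siteType, o), "")
  nPer <- c(intronic = sum(roles == "intronic"), fourfold = sum(roles == "exonic"))
  out <- list()
  for (pv in c("intronic", "fourfold")) {
    n <- as.integer(ceiling(params$controlFactor * params$nSites *
                              max(nPer[[pv]], 1L)))
    cols <- simulateColumns(n, params$mutationMatrix, rep(0, 4), params$ksRef,
                            params$ksSister, params$ksInner, params$ksOutgroup)
    score <- ifelse(runif(n) < 0.5, rnorm(n, 0, 0.3), rnorm(n, 0, 1.2))
    out[[pv]] <- new("ControlColumns", provenance = pv, ref = cols$ref,
                     sister = cols$sister, outgroup = cols$outgroup,
                     score = score)
  }
  out
}

#' Simulate a multispecies panel on a distance ladder
#'
#' For every site x offset of the ensemble design, generates extant states
#' for the reference species and for a ladder of panel species at the given
#' root-to-species Ks distances. States are correlated through shared path
#' lengths: species are evolved sequentially along the ladder, so species at
#' distance d_i and d_j (i < j) share the path up to d_i. With
#' `control = TRUE` a matched neutral panel of generic columns is generated
#' instead (one pseudo-offset, `controlFactor * nSites` columns).
#'
#' @param params a [simParams()] object.
#' @param distances non-decreasing Ks distances (default
#'   `params$panelDistances`).
#' @param control logical; generate the neutral control panel.
#' @return a [PanelEnsemble-class].
#' @export
simulatePanel <- function(params, distances = params$panelDistances,
                          control = FALSE) {
  stopifnot(inherits(params, "SimParams"))
  if (!length(distances)) stop("empty distance list")
  if (is.unsorted(distances)) stop("distances must be non-decreasing")
  set.seed(params$seed + if (control) 3L else 2L)
  st <- params$siteType
  steps <- diff(c(0, distances))
  ladder <- function(refStates, fitness) {
    out <- matrix(NA_integer_, length(refStates), length(distances))
    prev <- refStates
    for (j in seq_along(distances)) {
      prev <- evolveStates(prev, substitutionMatrix(steps[j],
                                                    params$mutationMatrix,
                                                    fitness))
      out[, j] <- prev
    }
    out
  }
  if (control) {
    n <- as.integer(ceiling(params$controlFactor * params$nSites))
    pi0 <- stationaryFrequencies(params$mutationMatrix, rep(0, 4))
    ref <- matrix(sample.int(4L, n, TRUE, pi0), n, 1)
    sp <- array(ladder(ref[, 1], rep(0, 4)), c(n, 1L, length(distances)))
    return(new("PanelEnsemble", siteType = "control", offsets = NA_integer_,
               distances = as.numeric(distances), ref = ref, species = sp))
  }
  n <- params$nSites
  offs <- params$offsets
  K <- length(offs)
  ref <- matrix(NA_integer_, n, K, dimnames = list(NULL, offs))
  sp <- array(NA_integer_, c(n, K, length(distances)))
  ssIdx <- integer(0)
  if (params$siteSpecificFraction > 0)
    ssIdx <- sort(sample.int(n, round(params$siteSpecificFraction * n)))
  for (j in seq_len(K)) {
    o <- offs[j]
    role <- roleOf(st, o)
    if (role == "invariant") {
      b <- match(invariantBase(st, o), NUC)
      ref[, j] <- b
      sp[, j, ] <- b
      next
    }
    Sj <- if (role == "no_consensus") 0 else params$S[[as.character(o)]]
    f0 <- offsetFitness(params$consensus, st, o, Sj)
    plain <- setdiff(seq_len(n), if (role == "no_consensus") integer(0) else ssIdx)
    groups <- list(list(idx = plain, fitness = f0))
    if (length(ssIdx) && role != "no_consensus") {
      nc <- setdiff(1:4, match(cnSet(params$consensus, st, o), NUC))
      fav <- nc[sample.int(length(nc), length(ssIdx), replace = TRUE)]
      for (a in unique(nc)) {
        fa <- f0
        fa[a] <- params$siteSpecificS
        idx <- ssIdx[fav == a]
        if (length(idx)) groups <- c(groups, list(list(idx = idx, fitness = fa)))
      }
    }
    for (g in groups) {
      if (!length(g$idx)) next
      pi <- stationaryFrequencies(params$mutationMatrix, g$fitness)
      r <- sample.int(4L, length(g$idx), TRUE, pi)
      ref[g$idx, j] <- r
      sp[g$idx, j, ] <- ladder(r, g$fitness)
    }
  }
  new("PanelEnsemble", siteType = st, offsets = as.integer(offs),
      distances = as.numeric(distances), ref = ref, species = sp)
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper bundling the triplet ensemble, the two neutral control
#' sets and (optionally) the multispecies panels for one site type.
#'
#' @param params a [simParams()] object.
#' @param panel logical; also simulate the multispecies panels.
#' @return list with `ensemble`, `controls` (list intronic/fourfold), and if
#'   requested `panel` and `panelControl`.
#' @export
simulateStudy <- function(params, panel = FALSE) {
  out <- list(ensemble = simulateTripletEnsemble(params),
              controls = simulateControls(params))
  if (panel) {
    out$panel <- simulatePanel(params)
    out$panelControl <- simulatePanel(params, control = TRUE)
  }
  out
}
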
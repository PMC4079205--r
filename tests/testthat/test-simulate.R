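test_that("stationary frequencies: neutral symmetry, selection and mutation balance", {
  m <- mutationMatrixKappa(2)
  expect_equal(unname(stationaryFrequencies(m, rep(0, 4))), rep(0.25, 4),
               tolerance = 1e-12)
  # two-allele reduction: symmetric mutation, advantage S -> freq ratio e^S
  m2 <- matrix(c(0, 1, 1, 0), 2)
  for (S in c(0.5, 2, -1.3)) {
    p <- stationaryFrequencies(m2, c(S, 0))
    expect_equal(p[1] / p[2], exp(S), tolerance = 1e-9)
  }
  # long-run Markov oracle: rows of P(t -> large) approach the stationary vector
  pS <- stationaryFrequencies(m, c(1, 0, -1, 0.5))
  Pinf <- substitutionMatrix(400, m, c(1, 0, -1, 0.5))
  expect_equal(unname(Pinf[1, ]), unname(pS), tolerance = 1e-8)
  # asymmetric mutation mu12 = 2 mu21, S = 0 -> freq1/freq2 = 1/2
  m21 <- matrix(c(0, 1, 2, 0), 2)  # rate 1->2 is 2, rate 2->1 is 1
  p <- stationaryFrequencies(m21, c(0, 0))
  expect_equal(p[1] / p[2], 1 / 2, tolerance = 1e-9)
  # absorbing / disconnected matrix is rejected
  expect_error(stationaryFrequencies(matrix(0, 4, 4), rep(0, 4)),
               "disconnected")
  expect_error(
    stationaryFrequencies(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                                c(0, 0, 0, 1), c(0, 0, 1, 0)), rep(0, 4)),
    "disconnected")
})

test_that("detailed balance holds for the selection-weighted rate matrix", {
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(runif(16, 0.2, 2), 4)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]  # symmetric mutation
    diag(m) <- 0
    S <- rnorm(4)
    pi <- stationaryFrequencies(m, S)
    Q <- spliceDrift:::rateMatrix(spliceDrift:::normalizeMutationMatrix(m), S)
    for (z in 1:3) for (x in (z + 1):4)
      expect_equal(pi[z] * Q[z, x], pi[x] * Q[x, z], tolerance = 1e-9)
  }
})

test_that("branch transition matrices are stochastic and selection-weighted", {
  m <- mutationMatrixKappa(2)
  expect_equal(substitutionMatrix(0, m, rep(0, 4)), diag(4))
  P <- substitutionMatrix(0.3, m, c(0, -1, 2, 0.5))
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
  # equal fitness for all alleles reduces to the neutral mutation process
  expect_equal(substitutionMatrix(0.2, m, rep(3, 4)),
               substitutionMatrix(0.2, m, rep(0, 4)), tolerance = 1e-10)
  # instantaneous rate ratio: advantage 2 of A over G
  dt <- 1e-7
  Pd <- substitutionMatrix(dt, m, c(2, 0, 0, 0))
  expect_equal(Pd["G", "A"] / Pd["A", "G"],
               (m["G", "A"] * 2.3130) / (m["A", "G"] * 0.31304),
               tolerance = 1e-4)
  expect_error(substitutionMatrix(-0.1, m, rep(0, 4)), ">= 0")
})

test_that("triplet ensembles honour limits: zero branches, strong selection, determinism", {
  cons <- defaultConsensus()
  p0 <- simParams(nSites = 200, siteType = "donor", S = -1,
                  ksRef = 0, ksSister = 0, ksInner = 0, ksOutgroup = 0,
                  seed = 5)
  e0 <- simulateTripletEnsemble(p0)
  sq <- siteSeqs(e0)
  expect_identical(sq$ref, sq$sister)
  expect_identical(sq$ref, sq$outgroup)
  # strong Cn advantage: single-Cn offsets are fixed for the consensus base
  pS <- simParams(nSites = 300, siteType = "donor", S = -50, seed = 6)
  eS <- simulateTripletEnsemble(pS)
  for (o in c(-2, -1, 4, 5, 6)) {
    cn <- match(cnSet(cons, "donor", o), NUC4)
    j <- match(o, offsets(eS))
    for (sp in c("ref", "sister", "outgroup"))
      expect_true(all(siteSeqs(eS)[[sp]][, j] == cn))
  }
  # canonical dinucleotides everywhere
  for (sp in c("ref", "sister", "outgroup")) {
    expect_true(all(siteSeqs(eS)[[sp]][, match(1, offsets(eS))] == 3))  # G
    expect_true(all(siteSeqs(eS)[[sp]][, match(2, offsets(eS))] == 4))  # T
  }
  # byte-identical reruns for identical params
  p <- simParams(nSites = 150, siteType = "acceptor", S = -2,
                 siteSpecificFraction = 0.3, seed = 11)
  e1 <- simulateTripletEnsemble(p)
  e2 <- simulateTripletEnsemble(p)
  expect_identical(siteSeqs(e1), siteSeqs(e2))
  expect_identical(groundTruth(e1), groundTruth(e2))
  expect_identical(simulateControls(p)$intronic@score,
                   simulateControls(p)$intronic@score)
})

test_that("neutral substitution fraction on the reference branch matches theory", {
  set.seed(17)
  m <- mutationMatrixKappa(2)
  n <- 1e5
  cols <- simulateColumns(n, m, rep(0, 4), ksRef = 0.05, ksSister = 0.03,
                          ksInner = 0.01, ksOutgroup = 0.06)
  P <- substitutionMatrix(0.05, m, rep(0, 4))
  pChange <- 1 - sum(rep(0.25, 4) * diag(P))
  obs <- mean(cols$ref != cols$anc)
  se <- sqrt(pChange * (1 - pChange) / n)
  expect_lt(abs(obs - pChange), 3 * se)
})

test_that("multispecies panels: zero distance, Markov limit, protected Nc alleles", {
  p <- simParams(nSites = 400, siteType = "donor", S = 0,
                 panelDistances = 0, seed = 21)
  pan <- simulatePanel(p)
  expect_equal(pan@species[, , 1], pan@ref, ignore_attr = TRUE)
  expect_error(simulatePanel(p, distances = numeric(0)), "empty")
  # neutral, large distance: match probability approaches stationary (0.25)
  p2 <- simParams(nSites = 6000, siteType = "donor", S = 0,
                  panelDistances = c(0.1, 60), seed = 22)
  pan2 <- simulatePanel(p2)
  j <- match(5, pan2@offsets)
  match2 <- mean(pan2@species[, j, 2] == pan2@ref[, j])
  expect_lt(abs(match2 - 0.25), 3 * sqrt(0.25 * 0.75 / 6000))
  # site-specific favored Nc: Nc reference columns stay conserved deeper than
  # the same class in a neutral control panel
  pf <- simParams(nSites = 3000, siteType = "donor", S = 0,
                  siteSpecificFraction = 1, siteSpecificS = 4, seed = 23)
  panF <- simulatePanel(pf)
  ctlF <- simulatePanel(pf, control = TRUE)
  cons <- defaultConsensus()
  res <- conservationContrast(panF, ctlF, cons, 5, class = "nc",
                              selector = "nuc", B = 0)
  expect_gt(res$c, 0.5)
})

test_that("simulation parameters are validated", {
  expect_error(simParams(nSites = 10, siteType = "donor"), "seed")
  expect_error(simParams(nSites = 10, siteType = "donor",
                         siteSpecificFraction = 1.5, seed = 1))
  expect_error(simParams(nSites = 10, siteType = "donor", ksRef = -1,
                         seed = 1))
  expect_error(simParams(nSites = 10, siteType = "donor",
                         S = c(`-3` = -1), seed = 1), "lacks offsets")
  # mutation matrix is normalized to one neutral substitution per Ks
  p <- simParams(nSites = 10, siteType = "donor", seed = 1,
                 mutationMatrix = matrix(5, 4, 4))
  pi0 <- stationaryFrequencies(p$mutationMatrix, rep(0, 4))
  expect_equal(sum(pi0 * rowSums(p$mutationMatrix)), 1, tolerance = 1e-10)
})
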
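test_that("parsimony ancestor matches brute-force enumeration on all 64 triplets", {
  for (r in 1:4) for (s in 1:4) for (o in 1:4) {
    got <- parsimonyAncestor(NUC4[r], NUC4[s], NUC4[o])
    expect_identical(got, bruteParsimony(r, s, o),
                     info = sprintf("triplet %s%s%s", NUC4[r], NUC4[s], NUC4[o]))
  }
  expect_identical(parsimonyAncestor("A", "A", "A"), "A")
  expect_identical(parsimonyAncestor("A", "G", "G"), "G")
  expect_true(is.na(parsimonyAncestor("A", "G", "C")))
  # missing data and gaps are ambiguous; junk symbols are an error
  expect_true(is.na(parsimonyAncestor("A", NA, "A")))
  expect_true(is.na(parsimonyAncestor("A", "-", "A")))
  expect_error(parsimonyAncestor("A", "X", "A"), "non-nucleotide")
})

test_that("substitution counting polarizes on the reference branch", {
  cons <- defaultConsensus()
  # 1000 identical triplets: all mass on the diagonal
  e <- makeEnsemble("donor", rep("CAGGTAAGT", 1000))
  cc <- countSubstitutions(e, cons)
  m <- countMatrix(cc, -3)
  expect_equal(m["C", "C"], 1000)
  expect_equal(sum(m) - m["C", "C"], 0)
  # ref G, sister A, outgroup A at offset -3 -> one A->G event
  e2 <- makeEnsemble("donor", ref = "GAGGTAAGT", sister = "AAGGTAAGT",
                     outgroup = "AAGGTAAGT")
  m2 <- countMatrix(countSubstitutions(e2, cons), -3)
  expect_equal(m2["A", "G"], 1)
  expect_equal(sum(m2), 1)
  # ambiguous columns contribute to no entry but are tallied
  e3 <- makeEnsemble("donor", ref = "TAGGTAAGT", sister = "GAGGTAAGT",
                     outgroup = "CAGGTAAGT")
  cc3 <- countSubstitutions(e3, cons)
  expect_equal(sum(countMatrix(cc3, -3)), 0)
  expect_equal(cc3@ambiguous[match(-3, cc3@offsets)], 1L)
  expect_error(
    countSubstitutions(new("SpliceSiteEnsemble", siteType = "donor",
                           offsets = offsets(e)[-1],
                           seqs = siteSeqs(e), info = siteInfo(e),
                           truth = list())),
    "offset")
})

test_that("ancestral CpG context exclusion removes both positions of the CG", {
  cons <- defaultConsensus()
  # donor -3..-1 = "ACG": ancestral C at -2 followed by G at -1 forms a CpG
  e <- makeEnsemble("donor", rep("ACGGTAAGT", 10))
  ccOn <- countSubstitutions(e, cons, excludeCpg = TRUE)
  ccOff <- countSubstitutions(e, cons, excludeCpg = FALSE)
  for (o in c(-2, -1)) {
    j <- match(o, ccOn@offsets)
    expect_equal(sum(ccOn@counts[, , j]), 0)
    expect_equal(ccOn@excluded[j], 10L)
    expect_equal(sum(ccOff@counts[, , j]), 10)
  }
  # position -3 (A) is untouched
  expect_equal(sum(countMatrix(ccOn, -3)), 10)
  # the invariant G at +1 puts +2 after G: "GT" is not a CpG; +3 A unaffected
  expect_equal(sum(countMatrix(ccOn, 3)), 10)
})

test_that("mass conservation: counts + ambiguous + excluded = records at every offset", {
  p <- simParams(nSites = 3000, siteType = "acceptor", S = -2,
                 siteSpecificFraction = 0.2, seed = 41)
  e <- simulateTripletEnsemble(p)
  for (flag in c(FALSE, TRUE)) {
    cc <- countSubstitutions(e, defaultConsensus(), excludeCpg = flag)
    tot <- apply(cc@counts, 3, sum) + cc@ambiguous + cc@excluded
    expect_true(all(tot == cc@nRecords))
  }
})

test_that("reconstructed ancestors rarely differ from the simulator's truth at short branches", {
  set.seed(43)
  m <- mutationMatrixKappa(2)
  cols <- simulateColumns(5e4, m, rep(0, 4), ksRef = 0.05, ksSister = 0.05,
                          ksInner = 0.01, ksOutgroup = 0.1)
  pa <- parsimonyAncestor(cols$ref, cols$sister, cols$outgroup)
  wrong <- mean(!is.na(pa) & match(pa, NUC4) != cols$anc)
  expect_lt(wrong, 0.01)
})

test_that("neutral rates: score filter, additivity, error on empty controls", {
  ctl <- new("ControlColumns", provenance = "intronic",
             ref = rep(1:4, 25), sister = rep(1:4, 25),
             outgroup = rep(1:4, 25),
             score = rep(c(0.1, 0.59, 0.61, 2.0), each = 25))
  nr <- neutralRates(ctl, threshold = 0.6)
  expect_equal(sum(nr@counts$intronic), 50)      # 2 of 4 score groups retained
  expect_equal(nr@nFiltered[["intronic"]], 50L)
  # complementary reading retains the other half
  nrHi <- neutralRates(ctl, threshold = 0.6, keepBelow = FALSE)
  expect_equal(sum(nrHi@counts$intronic), 50)
  expect_error(neutralRates(ctl, threshold = 0), "no control positions")
  # additivity over disjoint target sets
  p <- simParams(nSites = 800, siteType = "donor", seed = 44)
  nr2 <- neutralRates(simulateControls(p))
  rSplit <- sum(vapply(c("C", "G", "T"), function(x)
    neutralRate(nr2, "intronic", "A", x)$rate, numeric(1)))
  expect_equal(rSplit, neutralRate(nr2, "intronic", "A", c("C", "G", "T"))$rate,
               tolerance = 1e-12)
  # worked example: 2000 ancestral-A controls, 8 with A->G
  mA <- matrix(0, 4, 4); mA[1, 1] <- 1992; mA[1, 3] <- 8
  nrA <- makeNeutral(mA)
  expect_equal(neutralRate(nrA, "intronic", "A", "G")$rate, 0.004)
  expect_error(neutralRate(nrA, "intronic", "A", c("A", "G")), "source")
})

test_that("the CpG rate multiplier inflates rates and exclusion removes most of the excess", {
  cons <- defaultConsensus()
  p <- simParams(nSites = 20000, siteType = "acceptor", S = 0,
                 cpgRateMultiplier = 6, seed = 81)
  e <- simulateTripletEnsemble(p)
  nr <- neutralRates(simulateControls(p))
  excess <- vapply(c(FALSE, TRUE), function(flag) {
    ps <- pooledSelection(countSubstitutions(e, cons, excludeCpg = flag),
                          cons, nr, "CnToNc")
    ps$q / ps$qExp - 1
  }, numeric(1))
  expect_gt(excess[1], 0.25)               # hypermutability is visible
  expect_lt(excess[2], excess[1] / 3)      # exclusion removes most of it
})
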
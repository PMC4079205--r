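cons <- defaultConsensus()

test_that("class-exit frequencies follow the #(Z->X) count definitions", {
  # Cn = {A} at donor -2: q(Cn->Nc) = 10/1000
  mA <- matrix(0, 4, 4, dimnames = list(NUC4, NUC4))
  mA["A", "A"] <- 990; mA["A", "G"] <- 10
  cc <- makeCounts("donor", list(`-2` = mA))
  est <- classFrequency(cc, cons, -2, "CnToNc")
  expect_equal(est$q, 0.01)
  expect_equal(est$k, 10); expect_equal(est$n, 1000)
  # within-class move at a two-Cn offset counts toward n but not k
  mTC <- matrix(0, 4, 4, dimnames = list(NUC4, NUC4))
  mTC["T", "C"] <- 5; mTC["T", "T"] <- 95
  cc2 <- makeCounts("acceptor", list(`-10` = mTC))  # Cn = {T, C}
  est2 <- classFrequency(cc2, cons, -10, "CnToNc")
  expect_equal(est2$k, 0); expect_equal(est2$n, 100); expect_equal(est2$q, 0)
  # Nc->Cn pools over all nonconsensus ancestors
  mNc <- matrix(0, 4, 4, dimnames = list(NUC4, NUC4))
  mNc["G", "A"] <- 3; mNc["G", "G"] <- 45; mNc["G", "C"] <- 2
  mNc["C", "C"] <- 50
  cc3 <- makeCounts("donor", list(`-2` = mNc))      # Cn = {A}; Nc = {C,G,T}
  est3 <- classFrequency(cc3, cons, -2, "NcToCn")
  expect_equal(est3$k, 3); expect_equal(est3$n, 100)
  expect_equal(est3$q, 0.03)
  # invariant / no-consensus offsets are rejected
  expect_error(classFrequency(makeCounts("donor", list(`1` = mA)), cons, 1,
                              "CnToNc"), "no defined Cn")
})

test_that("class frequencies are invariant to relabeling within the Nc set", {
  m <- matrix(0, 4, 4, dimnames = list(NUC4, NUC4))
  m["A", ] <- c(900, 30, 20, 10)   # Cn = {A} at donor -2
  m["C", ] <- c(5, 40, 3, 2)
  m["G", ] <- c(7, 1, 60, 2)
  m["T", ] <- c(4, 2, 1, 30)
  ccA <- makeCounts("donor", list(`-2` = m))
  # swap the Nc labels C and T everywhere
  perm <- c(1, 4, 3, 2)
  m2 <- m[perm, perm]
  dimnames(m2) <- list(NUC4, NUC4)
  ccB <- makeCounts("donor", list(`-2` = m2))
  for (dir in c("CnToNc", "NcToCn")) {
    a <- classFrequency(ccA, cons, -2, dir)
    b <- classFrequency(ccB, cons, -2, dir)
    expect_equal(a$q, b$q)
    expect_equal(a$k, b$k)
    expect_equal(a$n, b$n)
  }
})

test_that("neutral expectation is the composition-weighted mean of matched control rates", {
  # donor +3 has Cn = {A, G} (intronic provenance)
  mObs <- matrix(0, 4, 4, dimnames = list(NUC4, NUC4))
  mObs["A", "A"] <- 700; mObs["G", "G"] <- 300
  cc <- makeCounts("donor", list(`3` = mObs))
  # control rates: r_A(Nc set) = 0.004, r_G(Nc set) = 0.006
  mCtl <- matrix(0, 4, 4)
  mCtl[1, 1] <- 996; mCtl[1, 2] <- 2; mCtl[1, 4] <- 2      # A: 4/1000
  mCtl[3, 3] <- 994; mCtl[3, 2] <- 3; mCtl[3, 4] <- 3      # G: 6/1000
  mCtl[2, 2] <- 500; mCtl[4, 4] <- 500
  nr <- makeNeutral(mCtl)
  exp <- expectedFrequency(cc, cons, 3, "CnToNc", nr)
  expect_equal(exp$qExp, 0.7 * 0.004 + 0.3 * 0.006, tolerance = 1e-12)
  expect_equal(exp$qExp, 0.0046, tolerance = 1e-12)
  expect_equal(exp$nExp, 1000)
  expect_identical(exp$provenance, "intronic")
  # single-nucleotide composition: qExp equals that nucleotide's control rate
  mOne <- matrix(0, 4, 4, dimnames = list(NUC4, NUC4))
  mOne["A", "A"] <- 500
  expOne <- expectedFrequency(makeCounts("donor", list(`-2` = mOne)), cons,
                              -2, "CnToNc", nr)
  expect_equal(expOne$qExp, 0.004, tolerance = 1e-12)
  expect_identical(expOne$provenance, "fourfold")  # exonic offset
})

test_that("Fisher obs-vs-exp test matches hypergeometric enumeration", {
  expect_equal(obsVsExpTest(10, 1000, 10, 1000), 1)
  expect_lt(obsVsExpTest(0, 100, 100, 100), 1e-20)
  for (tab in list(c(2, 10, 3, 10), c(5, 20, 1, 30), c(0, 10, 4, 12))) {
    expect_equal(obsVsExpTest(tab[1], tab[2], tab[3], tab[4]),
                 bruteFisherP(tab[1], tab[2] - tab[1], tab[3],
                              tab[4] - tab[3]),
                 tolerance = 1e-9,
                 info = paste(tab, collapse = ","))
  }
  expect_warning(p <- obsVsExpTest(0, 10, 0, 12), "degenerate")
  expect_equal(p, 1)
})

test_that("pooled class frequencies equal opportunity-weighted per-offset means", {
  p <- simParams(nSites = 4000, siteType = "donor", S = -2, seed = 51)
  cc <- countSubstitutions(simulateTripletEnsemble(p))
  nr <- neutralRates(simulateControls(p))
  pooled <- pooledSelection(cc, cons, nr, "CnToNc")
  per <- do.call(rbind, lapply(scoredOffsets(cons, "donor"), function(o)
    classFrequency(cc, cons, o, "CnToNc")))
  expect_equal(pooled$k, sum(per$k))
  expect_equal(pooled$n, sum(per$n))
  expect_equal(pooled$q, sum(per$n * per$q) / sum(per$n), tolerance = 1e-12)
})

test_that("neutral simulation: observed frequencies match the matched expectation", {
  p <- simParams(nSites = 8000, siteType = "donor", S = 0, seed = 52)
  cc <- countSubstitutions(simulateTripletEnsemble(p))
  nr <- neutralRates(simulateControls(p))
  tab <- selectionTable(cc, cons, nr)
  # q_obs - q_exp within 3 combined binomial SE of zero at every offset
  seObs <- sqrt(tab$q * (1 - tab$q) / tab$n)
  seExp <- sqrt(tab$qExp * (1 - tab$qExp) / (tab$n * p$controlFactor / 2))
  expect_true(all(abs(tab$q - tab$qExp) < 3 * sqrt(seObs^2 + seExp^2)))
})

test_that("selection-regime simulation shows the expected rate asymmetries", {
  p <- simParams(nSites = 2e4, siteType = "donor", S = -2, seed = 53)
  cc <- countSubstitutions(simulateTripletEnsemble(p))
  nr <- neutralRates(simulateControls(p))
  neg <- pooledSelection(cc, cons, nr, "CnToNc")
  pos <- pooledSelection(cc, cons, nr, "NcToCn")
  expect_lt(neg$q, neg$qExp)   # Cn protected by negative selection
  expect_gt(pos$q, pos$qExp)   # Nc replaced under positive selection
  pNeg <- obsVsExpTest(neg$k, neg$n, round(neg$qExp * 1e6), 1e6)
  pPos <- obsVsExpTest(pos$k, pos$n, round(pos$qExp * 1e6), 1e6)
  expect_lt(pNeg, 0.05)
  expect_lt(pPos, 0.05)
})
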
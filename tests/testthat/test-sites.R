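test_that("position roles and scored-offset counts follow the site architecture", {
  expect_identical(positionRole("donor", -1), "exonic")
  expect_identical(positionRole("donor", 1), "invariant")
  expect_identical(positionRole("acceptor", -2), "invariant")
  expect_identical(positionRole("acceptor", 1), "exonic")
  expect_identical(positionRole("acceptor", -4), "no_consensus")
  expect_identical(positionRole("acceptor", -24), "intronic")
  expect_error(positionRole("donor", 0), "outside")
  expect_error(positionRole("donor", 7), "outside")
  cons <- defaultConsensus()
  expect_length(scoredOffsets(cons, "donor"), 7)
  expect_length(scoredOffsets(cons, "acceptor"), 22)
  expect_setequal(scoredOffsets(cons, "donor"), c(-3:-1, 3:6))
  expect_false(-4 %in% scoredOffsets(cons, "acceptor"))
  expect_identical(cnSet(cons, "donor", 1), character(0))
})

test_that("consensus derivation: top-1/top-2 rule, forced roles, rescaling invariance", {
  fmDonor <- matrix(0.25, 9, 4, dimnames = list(c(-3:-1, 1:6), NUC4))
  fmDonor["-3", ] <- c(0.60, 0.30, 0.06, 0.04)            # single Cn = A
  fmDonor["-2", ] <- c(0.05, 0.40, 0.05, 0.50)            # T then C -> {T, C}
  fmDonor["4", ] <- c(0.70, 0.10, 0.15, 0.05)
  ct <- deriveConsensus(list(donor = fmDonor), secondaryThreshold = 0.35)
  expect_identical(cnSet(ct, "donor", -3), "A")
  expect_setequal(cnSet(ct, "donor", -2), c("T", "C"))
  expect_identical(cnSet(ct, "donor", -2)[1], "T")         # most frequent first
  expect_identical(cnSet(ct, "donor", 4), "A")
  # +1/+2 invariant regardless of the supplied frequencies
  expect_identical(positionRole("donor", 1), "invariant")
  expect_identical(cnSet(ct, "donor", 1), character(0))
  # invariance to frequency rescaling, and idempotence of the rule
  ct2 <- deriveConsensus(list(donor = fmDonor * 1000), secondaryThreshold = 0.35)
  expect_identical(ct@table, ct2@table)
  expect_error(deriveConsensus(list(donor = fmDonor[1:5, ])), "lacks offsets")
})

test_that("splice sites are extracted on the transcribed strand with canonical filtering", {
  paths <- writeToyGenome()
  sites <- parseSpliceSites(paths$gff, paths$fasta)
  don <- sites$donor
  acc <- sites$acceptor
  # the GC-donor intron of gene 2 is excluded; genes 1 and 3 remain
  expect_equal(nrow(siteInfo(don)), 2)
  expect_equal(nrow(siteInfo(acc)), 3)  # acceptors of genes 1, 2, 3 are AG
  seqs <- spliceDrift:::intToSeq(siteSeqs(don)$ref)
  expect_true(all(seqs == "CAGGTAAGT"))  # donor window -3..+6 by definition
  # minus-strand record equals the reverse complement of the genome slice
  minus <- which(siteInfo(don)$strand == "-")
  expect_length(minus, 1)
  expect_identical(seqs[minus], "CAGGTAAGT")
  # acceptor window: 24 intronic bases then the first exon base
  aseqs <- spliceDrift:::intToSeq(siteSeqs(acc)$ref)
  expect_true(all(substr(aseqs, 23, 25) == "AGG"))
  # labels: gene 1 has CDS -> coding; its exons are shared by both transcripts
  expect_true(all(siteInfo(don)$splicingClass == "constitutive"))
  g1 <- grep(":\\+:", siteInfo(don)$siteId)
  expect_true(any(siteInfo(don)$codingClass[g1] == "coding"))
})

test_that("site tables round-trip through TSV", {
  p <- simParams(nSites = 40, siteType = "donor", S = -1, seed = 3)
  e <- simulateTripletEnsemble(p)
  path <- tempfile(fileext = ".tsv")
  writeSiteTable(e, path)
  back <- readSiteTable(path)
  expect_identical(siteSeqs(back), siteSeqs(e))
  expect_identical(offsets(back), offsets(e))
  expect_identical(siteInfo(back)$siteId, siteInfo(e)$siteId)
  expect_identical(siteInfo(back)$codingClass, siteInfo(e)$codingClass)
  # controls round-trip too
  ctl <- simulateControls(p)
  cpath <- tempfile(fileext = ".tsv")
  writeControlTable(ctl, cpath)
  cback <- readControlTable(cpath)
  expect_identical(cback$intronic@ref, ctl$intronic@ref)
  expect_equal(cback$fourfold@score, ctl$fourfold@score, tolerance = 1e-9)
})

test_that("splice-site strength: Cn fraction and tertile classes", {
  cons <- defaultConsensus()
  # all-consensus donor: CAG|GTAAGT hits Cn at every scored offset
  e <- makeEnsemble("donor", rep("CAGGTAAGT", 3))
  e <- ssStrength(e, cons)
  expect_equal(siteInfo(e)$strengthFraction, rep(1, 3))
  # donor with 4 of 7 scored offsets consensus
  e2 <- ssStrength(makeEnsemble("donor", "TTGGTAAGA"), cons)
  expect_equal(siteInfo(e2)$strengthFraction, 4 / 7, tolerance = 1e-12)
  # ensemble tertiles: fractions 0.2/0.5/0.9 x 100 -> 100 sites per class
  frac <- rep(c(0.2, 0.5, 0.9), each = 100)
  lab <- stratify(frac, sprintf("s%03d", 1:300))
  expect_equal(as.vector(table(lab)[c("weak", "middle", "strong")]),
               rep(100L, 3))
})
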
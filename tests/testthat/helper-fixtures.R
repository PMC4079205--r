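NUC4 <- c("A", "C", "G", "T")

## build a SpliceSiteEnsemble from character sequence vectors
makeEnsemble <- function(siteType, ref, sister = ref, outgroup = ref) {
  toMat <- function(x) {
    m <- t(vapply(strsplit(toupper(x), ""), function(s) match(s, NUC4),
                  integer(nchar(x[1]))))
    m
  }
  offs <- if (siteType == "donor") c(-3:-1, 1:6) else c(-24:-1, 1)
  refM <- toMat(ref)
  stopifnot(ncol(refM) == length(offs))
  new("SpliceSiteEnsemble", siteType = siteType, offsets = as.integer(offs),
      seqs = list(ref = refM, sister = toMat(sister),
                  outgroup = toMat(outgroup)),
      info = data.frame(siteId = sprintf("s%04d", seq_along(ref)),
                        codingClass = "coding",
                        splicingClass = "constitutive"),
      truth = list())
}

## build a SubstitutionCounts object from a named list offset -> 4x4 matrix
makeCounts <- function(siteType, matrices, nRecords = NULL) {
  offs <- as.integer(names(matrices))
  arr <- array(0L, c(4, 4, length(offs)),
               dimnames = list(NUC4, NUC4, offs))
  for (i in seq_along(offs)) arr[, , i] <- as.integer(matrices[[i]])
  tot <- vapply(matrices, sum, numeric(1))
  if (is.null(nRecords)) nRecords <- max(tot)
  new("SubstitutionCounts", siteType = siteType, offsets = offs,
      counts = arr, ambiguous = integer(length(offs)),
      excluded = as.integer(nRecords - tot), nRecords = as.integer(nRecords))
}

## NeutralRates with prescribed count matrices
makeNeutral <- function(intronic, fourfold = intronic) {
  dimnames(intronic) <- dimnames(fourfold) <- list(NUC4, NUC4)
  new("NeutralRates", counts = list(intronic = intronic, fourfold = fourfold),
      nFiltered = c(intronic = 0L, fourfold = 0L), threshold = 0.6,
      keepBelow = TRUE)
}

## PanelEnsemble from an explicit site x offset x species state array
makePanel <- function(siteType, offsets, distances, ref, speciesArr) {
  new("PanelEnsemble", siteType = siteType, offsets = as.integer(offsets),
      distances = distances, ref = ref, species = speciesArr)
}

## tiny two-gene GFF3 + FASTA fixture; returns paths and expectations
writeToyGenome <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  ex1 <- paste0(strrep("A", 27), "CAG")                     # exon tail CAG
  intron <- paste0("GTAAGT", strrep("T", 18), "TTTCAG")     # 30 bp
  ex2 <- paste0("G", strrep("A", 29))
  plusGene <- paste0(ex1, intron, ex2)                      # 90 bp at 11..100
  gcIntron <- paste0("GCAAGT", strrep("T", 18), "TTTCAG")
  plusGene2 <- paste0(ex1, gcIntron, ex2)                   # at 111..200
  minusPiece <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(plusGene)))                       # at 211..300
  chr <- paste0(strrep("C", 10), plusGene, strrep("C", 10), plusGene2,
                strrep("C", 10), minusPiece, strrep("C", 10))
  fa <- file.path(dir, "genome.fa")
  writeLines(c(">chr1 test", chr), fa)
  gff <- file.path(dir, "ann.gff3")
  attrs <- function(tx, g) sprintf("ID=%s.e;Parent=%s;transcript_id=%s;gene_id=%s",
                                   tx, tx, tx, g)
  rows <- c(
    "##gff-version 3",
    # gene 1 (+): two transcripts sharing both exons -> constitutive
    sprintf("chr1\ttoy\texon\t11\t40\t.\t+\t.\t%s", attrs("tx1", "g1")),
    sprintf("chr1\ttoy\texon\t71\t100\t.\t+\t.\t%s", attrs("tx1", "g1")),
    sprintf("chr1\ttoy\tCDS\t11\t100\t.\t+\t0\t%s", attrs("tx1", "g1")),
    sprintf("chr1\ttoy\texon\t11\t40\t.\t+\t.\t%s", attrs("tx1b", "g1")),
    sprintf("chr1\ttoy\texon\t71\t100\t.\t+\t.\t%s", attrs("tx1b", "g1")),
    # gene 2 (+): GC donor, must be filtered out
    sprintf("chr1\ttoy\texon\t111\t140\t.\t+\t.\t%s", attrs("tx2", "g2")),
    sprintf("chr1\ttoy\texon\t171\t200\t.\t+\t.\t%s", attrs("tx2", "g2")),
    # gene 3 (-): mirrored copy of gene 1
    sprintf("chr1\ttoy\texon\t211\t240\t.\t-\t.\t%s", attrs("tx3", "g3")),
    sprintf("chr1\ttoy\texon\t271\t300\t.\t-\t.\t%s", attrs("tx3", "g3")))
  writeLines(rows, gff)
  list(fasta = fa, gff = gff)
}

## brute-force parsimony oracle: minimize changes over (root, anc) assignments
## on the rooted tree (root -> outgroup, root -> anc, anc -> ref, anc -> sister)
bruteParsimony <- function(ref, sister, outgroup) {
  best <- Inf
  ancSet <- integer(0)
  for (anc in 1:4) for (root in 1:4) {
    cost <- (root != anc) + (anc != ref) + (anc != sister) + (root != outgroup)
    if (cost < best) { best <- cost; ancSet <- anc }
    else if (cost == best) ancSet <- union(ancSet, anc)
  }
  if (length(ancSet) == 1L) NUC4[ancSet] else NA_character_
}

## exhaustive two-sided Fisher p over tables with fixed margins
bruteFisherP <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  av <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- dhyper(av, c1, n - c1, r1)
  pObs <- dhyper(a, c1, n - c1, r1)
  sum(pr[pr <= pObs * (1 + 1e-7)])
}
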
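## Splice-site extraction from annotation + genome, strength classes, TSV IO.

seqToInt <- function(x, K) {
  m <- matrix(match(unlist(strsplit(toupper(x), "")), NUC),
              nrow = length(x), ncol = K, byrow = TRUE)
  m
}

intToSeq <- function(m) {
  s <- NUC[m]
  s[is.na(s)] <- "N"
  apply(matrix(s, nrow(m), ncol(m)), 1, paste, collapse = "")
}

#' Extract splice-site records from annotation and genome
#'
#' Walks every transcript's exon chain, emits one donor and one acceptor
#' record per intron on the transcribed strand (donor offsets -3..+6,
#' acceptor -24..+1), collapses duplicate sites shared by transcripts (by
#' genomic boundary coordinate + strand), and removes sites not carrying the
#' canonical GT/AG dinucleotides in the reference or, when alignments are
#' supplied, in any species. Records on transcripts with undefined strand are
#' skipped with a warning; exons outside the genome sequence are an error.
#'
#' An intron is labeled `coding` when it lies within the transcript's CDS
#' span and `noncoding` otherwise; splicing class is `constitutive` when the
#' flanking exons are present in every transcript of the gene (see
#' [constitutiveExons()]), else `cassette`.
#'
#' @param annotation path to a GFF3/GTF file (exon and optional CDS
#'   features).
#' @param genome path to the genome FASTA.
#' @param alignments optional named list with elements `sister` and
#'   `outgroup`: paths to (or `DNAStringSet`s of) aligned FASTA whose names
#'   are site ids (`chrom:boundary:strand:type`) and whose sequences cover
#'   the same offset ranges; sites missing from either species are dropped.
#' @return named list of [SpliceSiteEnsemble-class] objects (`donor`,
#'   `acceptor`).
#' @export
parseSpliceSites <- function(annotation, genome, alignments = NULL) {
  gff <- rtracklayer::import(annotation)
  gen <- Biostrings::readDNAStringSet(genome)
  names(gen) <- sub("\\s.*", "", names(gen))
  ex <- gff[tolower(as.character(gff$type)) == "exon"]
  txOf <- function(gr) {
    if (!is.null(gr$transcript_id)) as.character(gr$transcript_id)
    else if (!is.null(gr$Parent)) as.character(unlist(gr$Parent))
    else stop("annotation lacks transcript_id/Parent on exons")
  }
  tx <- txOf(ex)
  gene <- if (!is.null(ex$gene_id)) as.character(ex$gene_id) else tx
  cds <- gff[tolower(as.character(gff$type)) == "cds"]
  cdsSpan <- if (length(cds)) {
    ctx <- txOf(cds)
    lapply(split(seq_along(cds), ctx), function(i)
      c(min(GenomicRanges::start(cds[i])), max(GenomicRanges::end(cds[i]))))
  } else list()
  consTab <- constitutiveExons(ex, tx, gene)

  rows <- list()
  for (t in unique(tx)) {
    sel <- which(tx == t)
    e <- ex[sel]
    str <- unique(as.character(GenomicRanges::strand(e)))
    if (length(str) != 1 || str == "*") {
      warning("transcript ", t, " has unknown strand; skipped")
      next
    }
    chrom <- as.character(GenomicRanges::seqnames(e))[1]
    if (!chrom %in% names(gen)) stop("chromosome ", chrom, " not in genome")
    glen <- length(gen[[chrom]])
    if (any(GenomicRanges::end(e) > glen) || any(GenomicRanges::start(e) < 1))
      stop("exon outside genome bounds on ", chrom)
    o <- order(GenomicRanges::start(e))
    e <- e[o]
    if (length(e) < 2) next
    span <- cdsSpan[[t]]
    starts <- GenomicRanges::start(e); ends <- GenomicRanges::end(e)
    exKey <- paste(chrom, starts, ends, str)
    for (i in seq_len(length(e) - 1)) {
      i0 <- ends[i] + 1L          # first intron base (genomic)
      i1 <- starts[i + 1] - 1L    # last intron base (genomic)
      if (i1 < i0) next
      coding <- if (is.null(span)) "noncoding"
      else if (i0 > span[1] && i1 < span[2]) "coding" else "noncoding"
      splicing <- if (consTab[[exKey[i]]] && consTab[[exKey[i + 1]]])
        "constitutive" else "cassette"
      if (str == "+") {
        don <- c(chrom, i0, "+", i0 - 3L, i0 + 5L)
        acc <- c(chrom, i1, "+", i1 - 23L, i1 + 1L)
      } else {
        don <- c(chrom, i1, "-", i1 - 5L, i1 + 3L)
        acc <- c(chrom, i0, "-", i0 - 1L, i0 + 23L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        siteType = c("donor", "acceptor"), chrom = chrom,
        boundary = as.integer(c(don[2], acc[2])), strand = str,
        from = as.integer(c(don[4], acc[4])), to = as.integer(c(don[5], acc[5])),
        codingClass = coding, splicingClass = splicing)
    }
  }
  if (!length(rows)) stop("no introns found in annotation")
  tab <- do.call(rbind, rows)
  tab <- tab[!duplicated(tab[, c("siteType", "chrom", "boundary", "strand")]), ]

  out <- list()
  for (st in c("donor", "acceptor")) {
    sub <- tab[tab$siteType == st, ]
    if (!nrow(sub)) next
    offs <- siteOffsets(st)
    K <- length(offs)
    keep <- sub$from >= 1
    sub <- sub[keep, , drop = FALSE]
    seqs <- vapply(seq_len(nrow(sub)), function(i) {
      s <- as.character(Biostrings::subseq(gen[[sub$chrom[i]]], sub$from[i],
                                           sub$to[i]))
      if (sub$strand[i] == "-")
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      s
    }, "")
    ids <- paste(sub$chrom, sub$boundary, sub$strand, st, sep = ":")
    refM <- seqToInt(seqs, K)
    getAln <- function(which) {
      if (is.null(alignments) || is.null(alignments[[which]]))
        return(matrix(NA_integer_, nrow(sub), K))
      a <- alignments[[which]]
      if (is.character(a)) a <- Biostrings::readDNAStringSet(a)
      m <- matrix(NA_integer_, nrow(sub), K)
      hit <- match(ids, names(a))
      ok <- !is.na(hit)
      if (any(ok)) m[ok, ] <- seqToInt(as.character(a[hit[ok]]), K)
      m
    }
    sisM <- getAln("sister")
    outM <- getAln("outgroup")
    canonical <- function(m) {
      inv <- offs[vapply(offs, function(o) roleOf(st, o) == "invariant",
                         NA)]
      j <- match(inv, offs)
      want <- match(vapply(inv, function(o) invariantBase(st, o), ""), NUC)
      apply(m[, j, drop = FALSE], 1, function(r)
        all(is.na(r) | r == want) && !all(is.na(r)))
    }
    keep <- canonical(refM)
    if (!is.null(alignments)) {
      present <- !is.na(sisM[, 1]) & !is.na(outM[, 1])
      keep <- keep & present & canonical(sisM) & canonical(outM)
    }
    sub <- sub[keep, , drop = FALSE]
    info <- data.frame(siteId = ids[keep], codingClass = sub$codingClass,
                       splicingClass = sub$splicingClass,
                       chrom = sub$chrom, boundary = sub$boundary,
                       strand = sub$strand)
    out[[st]] <- new("SpliceSiteEnsemble", siteType = st,
                     offsets = as.integer(offs),
                     seqs = list(ref = refM[keep, , drop = FALSE],
                                 sister = sisM[keep, , drop = FALSE],
                                 outgroup = outM[keep, , drop = FALSE]),
                     info = info, truth = list())
  }
  out
}

#' Constitutive-exon inference from transcript structure
#'
#' An exon is constitutive when it is present (by identical coordinates) in
#' every transcript of its gene.
#'
#' @param exons GRanges of exon features.
#' @param tx,gene character vectors of transcript and gene ids per exon.
#' @return named logical vector keyed by "chrom start end strand".
#' @export
constitutiveExons <- function(exons, tx, gene) {
  key <- paste(as.character(GenomicRanges::seqnames(exons)),
               GenomicRanges::start(exons), GenomicRanges::end(exons),
               as.character(GenomicRanges::strand(exons)))
  res <- logical(0)
  for (g in unique(gene)) {
    sel <- gene == g
    txs <- unique(tx[sel])
    cnt <- table(unique(data.frame(k = key[sel], t = tx[sel]))$k)
    res[names(cnt)] <- as.integer(cnt) == length(txs)
  }
  res
}

#' Splice-site strength: Cn fraction and tertile class
#'
#' The strength fraction of a site is the share of scored offsets whose
#' reference nucleotide belongs to the offset's Cn set. Sites are binned into
#' weak / middle / strong classes at the ensemble tertiles of the fraction
#' (so roughly equal numbers fall into each class), or at user-supplied
#' bounds.
#'
#' @param ensemble a [SpliceSiteEnsemble-class].
#' @param consensus a [ConsensusTable-class].
#' @param tertileBounds optional numeric length-2 cut points.
#' @return the ensemble with `strengthFraction` and `strengthClass` columns
#'   added to its site info (bounds in `attr(siteInfo(x), "tertileBounds")`).
#' @export
ssStrength <- function(ensemble, consensus = defaultConsensus(),
                       tertileBounds = NULL) {
  st <- ensemble@siteType
  offs <- scoredOffsets(consensus, st)
  idx <- match(offs, ensemble@offsets)
  m <- ensemble@seqs$ref[, idx, drop = FALSE]
  isCn <- matrix(FALSE, nrow(m), ncol(m))
  for (j in seq_along(offs))
    isCn[, j] <- m[, j] %in% match(cnSet(consensus, st, offs[j]), NUC)
  frac <- rowMeans(isCn)
  if (is.null(tertileBounds))
    tertileBounds <- quantile(frac, c(1, 2) / 3, type = 1, names = FALSE)
  cls <- ifelse(frac <= tertileBounds[1], "weak",
                ifelse(frac <= tertileBounds[2], "middle", "strong"))
  info <- ensemble@info
  info$strengthFraction <- frac
  info$strengthClass <- cls
  attr(info, "tertileBounds") <- tertileBounds
  ensemble@info <- info
  ensemble
}

#' Subset an ensemble by site index
#'
#' @param ensemble a [SpliceSiteEnsemble-class].
#' @param idx integer or logical site index.
#' @return the subsetted ensemble.
#' @export
subsetEnsemble <- function(ensemble, idx) {
  ensemble@seqs <- lapply(ensemble@seqs, function(m) m[idx, , drop = FALSE])
  ensemble@info <- ensemble@info[idx, , drop = FALSE]
  if (length(ensemble@truth))
    ensemble@truth <- lapply(ensemble@truth, function(m)
      if (is.matrix(m)) m[idx, , drop = FALSE] else m)
  ensemble
}

#' Write / read the site table TSV
#'
#' Columns: siteId, siteType, codingClass, splicingClass, optional strength
#' and coordinate columns, and the per-species sequences over the offset
#' range. Reading back yields an equivalent [SpliceSiteEnsemble-class]
#' (ground truth is not serialized).
#'
#' @param ensemble a [SpliceSiteEnsemble-class].
#' @param path file path.
#' @return `readSiteTable` returns the ensemble; `writeSiteTable` the path,
#'   invisibly.
#' @export
writeSiteTable <- function(ensemble, path) {
  info <- ensemble@info
  attr(info, "tertileBounds") <- NULL
  df <- cbind(siteType = ensemble@siteType, info,
              seqRef = intToSeq(ensemble@seqs$ref),
              seqSister = intToSeq(ensemble@seqs$sister),
              seqOutgroup = intToSeq(ensemble@seqs$outgroup))
  con <- file(path, "w")
  writeLines(sprintf("# spliceDrift site table; offsets %s",
                     paste(ensemble@offsets, collapse = ",")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeSiteTable
#' @export
readSiteTable <- function(path) {
  header <- readLines(path, n = 1)
  offs <- as.integer(strsplit(sub(".*offsets ", "", header), ",")[[1]])
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  st <- unique(df$siteType)
  stopifnot(length(st) == 1)
  K <- length(offs)
  seqCols <- c("seqRef", "seqSister", "seqOutgroup")
  info <- df[, setdiff(names(df), c("siteType", seqCols)), drop = FALSE]
  dn <- list(NULL, offs)
  toM <- function(x) {
    m <- seqToInt(x, K)
    dimnames(m) <- dn
    m
  }
  new("SpliceSiteEnsemble", siteType = st, offsets = offs,
      seqs = list(ref = toM(df$seqRef), sister = toM(df$seqSister),
                  outgroup = toM(df$seqOutgroup)),
      info = info, truth = list())
}

#' Write substitution counts as long-format TSV
#'
#' Columns: siteType, offset, ancestral, descendant, count, plus per-offset
#' ambiguous/excluded tallies in '#' metadata lines.
#'
#' @param counts a [SubstitutionCounts-class].
#' @param path file path.
#' @export
writeCountsTable <- function(counts, path) {
  rows <- do.call(rbind, lapply(seq_along(counts@offsets), function(j) {
    m <- counts@counts[, , j]
    data.frame(siteType = counts@siteType, offset = counts@offsets[j],
               ancestral = rep(NUC, 4), descendant = rep(NUC, each = 4),
               count = as.vector(m))
  }))
  con <- file(path, "w")
  writeLines(c(sprintf("# nRecords=%d", counts@nRecords),
               sprintf("# offset=%d ambiguous=%d excluded=%d",
                       counts@offsets, counts@ambiguous, counts@excluded)),
             con)
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Write / read control columns TSV
#'
#' Columns: provenance, ref, sister, outgroup, score.
#'
#' @param controls list of [ControlColumns-class].
#' @param path file path.
#' @export
writeControlTable <- function(controls, path) {
  if (is(controls, "ControlColumns")) controls <- list(controls)
  df <- do.call(rbind, lapply(controls, function(x)
    data.frame(provenance = x@provenance, ref = NUC[x@ref],
               sister = NUC[x@sister], outgroup = NUC[x@outgroup],
               score = x@score)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeControlTable
#' @export
readControlTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  lapply(split(df, df$provenance), function(s)
    new("ControlColumns", provenance = s$provenance[1],
        ref = match(s$ref, NUC), sister = match(s$sister, NUC),
        outgroup = match(s$outgroup, NUC), score = s$score))
}
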
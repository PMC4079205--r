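## Pipeline orchestration: simulate/load -> reconstruct -> count -> infer ->
## conserve -> report, with stratification and a reproducibility manifest.

#' Stratify sites by a covariate
#'
#' Assigns tertile (or n-quantile) labels by covariate rank, with ties broken
#' deterministically by site-id order. Sites with missing covariate are
#' dropped with a warning; a constant covariate yields a single stratum with
#' a warning.
#'
#' @param covariate numeric vector, one value per site.
#' @param siteId character ids used for deterministic tie-breaking.
#' @param nStrata number of quantile bins (default 3; 2 gives a median
#'   split).
#' @param labels optional labels (default `"q1"..` or weak/middle/strong for
#'   3).
#' @return character vector of stratum labels (NA where dropped).
#' @export
stratify <- function(covariate, siteId = seq_along(covariate), nStrata = 3,
                     labels = NULL) {
  n <- length(covariate)
  lab <- rep(NA_character_, n)
  ok <- !is.na(covariate)
  if (any(!ok))
    warning(sum(!ok), " sites dropped: missing covariate")
  if (!any(ok)) return(lab)
  if (length(unique(covariate[ok])) == 1L) {
    warning("constant covariate; single stratum")
    lab[ok] <- "all"
    return(lab)
  }
  if (is.null(labels))
    labels <- if (nStrata == 3) c("weak", "middle", "strong")
    else paste0("q", seq_len(nStrata))
  ord <- order(covariate[ok], siteId[ok])
  rk <- integer(sum(ok))
  rk[ord] <- seq_len(sum(ok))
  lab[ok] <- labels[ceiling(rk * nStrata / sum(ok))]
  lab
}

defaultRunConfig <- function() {
  list(mode = "synthetic", siteTypes = c("donor", "acceptor"), nSites = 2000,
       S = 0, siteSpecificFraction = 0, siteSpecificS = 2, kappa = 2,
       ksRef = 0.03, ksSister = 0.03, ksInner = 0.01, ksOutgroup = 0.06,
       controlFactor = 10, codingFraction = 0.8, cpgRateMultiplier = 1,
       excludeCpg = FALSE, scoreThreshold = 0.6, keepBelow = TRUE,
       alpha = 0.05, B = 1000, Ne = 1e4, genomeSiteCount = NULL,
       panel = FALSE, panelOffsets = NULL, stratifier = NULL, seed = NULL,
       siteTable = NULL, controlTable = NULL, outDir = NULL)
}

loadRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- defaultRunConfig()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(config)] <- config
  if (cfg$mode == "synthetic" && is.null(cfg$seed))
    stop("seed is mandatory in synthetic mode", call. = FALSE)
  if (cfg$mode == "real" &&
      (is.null(cfg$siteTable) || is.null(cfg$controlTable)))
    stop("real mode requires siteTable and controlTable paths", call. = FALSE)
  if (cfg$mode == "real")
    for (p in c(cfg$siteTable, cfg$controlTable))
      if (!file.exists(p)) stop("input not found: ", p, call. = FALSE)
  cfg
}

analyzeType <- function(ensemble, controls, cfg, consensus, params = NULL) {
  ensemble <- ssStrength(ensemble, consensus)
  counts <- countSubstitutions(ensemble, consensus,
                               excludeCpg = isTRUE(cfg$excludeCpg))
  neutral <- neutralRates(controls, threshold = cfg$scoreThreshold,
                          keepBelow = cfg$keepBelow)
  sel <- selectionTable(counts, consensus, neutral, alpha = cfg$alpha)
  pooled <- do.call(rbind, lapply(c("CnToNc", "NcToCn"), function(d)
    cbind(direction = d,
          pooledSelection(counts, consensus, neutral, d, cfg$alpha))))
  nc <- ncSummary(ensemble, consensus)
  nSS <- if (!is.null(cfg$genomeSiteCount)) cfg$genomeSiteCount
  else nrow(ensemble@info)
  sNeg <- abs(pooled$SHat[pooled$direction == "CnToNc"])
  load <- cbind(driftLoad(nSS, nc$meanNc,
                          perLocusS(ifelse(is.finite(sNeg), sNeg, NA), cfg$Ne)),
                cnFraction = nc$cnFraction)
  strata <- NULL
  if (!is.null(cfg$stratifier)) {
    lab <- switch(cfg$stratifier,
      strength_class = ensemble@info$strengthClass,
      coding_class = ensemble@info$codingClass,
      splicing_class = ensemble@info$splicingClass,
      stop("unknown stratifier: ", cfg$stratifier))
    strata <- lapply(split(seq_along(lab), lab), function(idx) {
      sub <- subsetEnsemble(ensemble, idx)
      cSub <- countSubstitutions(sub, consensus,
                                 excludeCpg = isTRUE(cfg$excludeCpg))
      list(n = length(idx),
           selection = selectionTable(cSub, consensus, neutral, cfg$alpha))
    })
  }
  conservation <- NULL
  if (isTRUE(cfg$panel) && !is.null(params)) {
    panel <- simulatePanel(params)
    panelCtl <- simulatePanel(params, control = TRUE)
    offs <- cfg$panelOffsets
    if (is.null(offs)) offs <- scoredOffsets(consensus, ensemble@siteType)
    conservation <- do.call(rbind, lapply(offs, function(o)
      do.call(rbind, lapply(c("nuc", "set"), function(sl)
        conservationContrast(panel, panelCtl, consensus, o, class = "nc",
                             selector = sl, B = cfg$B)))))
  }
  list(ensemble = ensemble, counts = counts, neutral = neutral,
       selection = sel, pooled = pooled, load = load, strata = strata,
       conservation = conservation,
       funnel = c(records = counts@nRecords,
                  ambiguousColumns = sum(counts@ambiguous),
                  excludedColumns = sum(counts@excluded)))
}

#' Run the full inference pipeline
#'
#' Orchestrates, per site type: data generation (synthetic mode) or loading
#' (real mode: site/control TSV tables), strength classification, parsimony
#' reconstruction and substitution counting, per-offset and pooled selection
#' estimation against the neutral controls, optional stratified analyses and
#' multispecies conservation contrasts, and the drift-load summary. Re-running
#' with an identical config reproduces identical outputs; a manifest (config
#' hash, seed, package version) records provenance.
#'
#' @param config a config list or path to a YAML config file. See
#'   [runConfigTemplate()] for the schema and defaults.
#' @return a report bundle: list with `config`, `manifest`, and one entry per
#'   site type holding `selection`, `pooled`, `load`, `funnel`, and (if
#'   requested) `strata` and `conservation` tables.
#' @export
runPipeline <- function(config = list()) {
  cfg <- loadRunConfig(config)
  consensus <- defaultConsensus()
  bundle <- list(config = cfg)
  if (cfg$mode == "synthetic") {
    for (i in seq_along(cfg$siteTypes)) {
      st <- cfg$siteTypes[i]
      params <- simParams(nSites = cfg$nSites, siteType = st, S = cfg$S,
                          consensus = consensus,
                          siteSpecificFraction = cfg$siteSpecificFraction,
                          siteSpecificS = cfg$siteSpecificS,
                          mutationMatrix = mutationMatrixKappa(cfg$kappa),
                          ksRef = cfg$ksRef, ksSister = cfg$ksSister,
                          ksInner = cfg$ksInner, ksOutgroup = cfg$ksOutgroup,
                          controlFactor = cfg$controlFactor,
                          codingFraction = cfg$codingFraction,
                          cpgRateMultiplier = cfg$cpgRateMultiplier,
                          seed = cfg$seed + 10L * i)
      study <- simulateStudy(params)
      bundle[[st]] <- withStage(st, analyzeType(study$ensemble,
                                                study$controls, cfg,
                                                consensus, params))
    }
  } else {
    ensemble <- readSiteTable(cfg$siteTable)
    controls <- readControlTable(cfg$controlTable)
    bundle[[ensemble@siteType]] <-
      withStage(ensemble@siteType,
                analyzeType(ensemble, controls, cfg, consensus))
  }
  bundle$manifest <- runManifest(cfg)
  if (!is.null(cfg$outDir)) writeRunOutputs(bundle, cfg$outDir)
  bundle
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", stage, "] failed: ", conditionMessage(e), call. = FALSE))
}

runManifest <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg[!vapply(cfg, is.null, NA)], tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  list(configHash = h, seed = cfg$seed,
       package = as.character(packageVersion("spliceDrift")),
       rVersion = R.version.string)
}

#' Print the run-config schema with defaults
#'
#' @return the default config list, invisibly (printed as YAML).
#' @export
runConfigTemplate <- function() {
  cfg <- defaultRunConfig()
  cat(yaml::as.yaml(cfg[!vapply(cfg, is.null, NA)]))
  cat("# plus optional: genomeSiteCount, panelOffsets, stratifier,",
      "siteTable, controlTable, outDir\n")
  invisible(cfg)
}

writeRunOutputs <- function(bundle, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  meta <- function(path, df) {
    con <- file(path, "w")
    writeLines(sprintf("# spliceDrift %s; configHash=%s; seed=%s",
                       bundle$manifest$package, bundle$manifest$configHash,
                       bundle$manifest$seed), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  for (st in intersect(c("donor", "acceptor"), names(bundle))) {
    res <- bundle[[st]]
    meta(file.path(outDir, paste0(st, "_selection.tsv")), res$selection)
    meta(file.path(outDir, paste0(st, "_pooled.tsv")), res$pooled)
    meta(file.path(outDir, paste0(st, "_load.tsv")), res$load)
    writeCountsTable(res$counts, file.path(outDir, paste0(st, "_counts.tsv")))
    if (!is.null(res$conservation))
      meta(file.path(outDir, paste0(st, "_conservation.tsv")),
           res$conservation)
    if (!is.null(res$strata))
      for (nm in names(res$strata))
        meta(file.path(outDir, paste0(st, "_selection_", nm, ".tsv")),
             res$strata[[nm]]$selection)
  }
  yaml::write_yaml(c(bundle$manifest,
                     list(funnel = lapply(bundle[intersect(
                       c("donor", "acceptor"), names(bundle))],
                       function(x) as.list(x$funnel)))),
                   file.path(outDir, "manifest.yaml"))
  invisible(outDir)
}
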
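#' Run the full cross-platform evaluation pipeline
#'
#' Orchestrates the stages end to end: simulate (or load) a multi-platform
#' titration study, derive transcript patterns (probe-level runs),
#' normalize and make detection calls, compute the signal-domain metrics,
#' fold-change metrics and compression against a reference platform, and
#' optionally the qRT-PCR concordance stage. Writes a machine-readable
#' JSON summary plus TSV tables and returns the result invisibly.
#'
#' The config is a nested list (or a path to a YAML file with the same
#' shape). Recognized entries, all optional unless noted:
#'
#' * `seed` — integer, drives every random stage (default 1).
#' * `simulate` — list(`nGenes`, `probeLevel`, `decoyFraction`, plus any
#'   [simulateTruth()] parameter); if absent, `inputs` must give paths.
#' * `inputs` — list(`design` YAML path, `matrices` = named list of
#'   list(`path`, `kind`) per platform, optional `annotation` GTF and
#'   `probes` named list of BED paths).
#' * `referencePlatform` — platform for compression regression (default
#'   `"arrayA"`).
#' * `thresholds` — list(`fidelity` = 0.5, `cpmDetection` = 0.25,
#'   `pDetection` = 0.05, `pseudocount` = 1).
#' * `ct` — list(`table` data.frame or `path` TSV, `housekeeping`,
#'   `referenceSample`, optional `platformSample` contrast sample,
#'   default `"BMO"`).
#'
#' @param config list or YAML path.
#' @param outdir output directory (created if needed).
#' @return (invisibly) list with elements `study`, `patterns`,
#'   `normalized`, `detection`, `signalMetrics`, `foldChange`,
#'   `concordance`, `accounting`, `summary`.
#' @export
runPipeline <- function(config = list(), outdir = tempfile("titbench")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  thr <- config$thresholds %||% list()
  thr$fidelity <- thr$fidelity %||% 0.5
  thr$cpmDetection <- thr$cpmDetection %||% 0.25
  thr$pDetection <- thr$pDetection %||% 0.05
  thr$pseudocount <- thr$pseudocount %||% 1
  refPlat <- config$referencePlatform %||% "arrayA"
  stopifnot(length(refPlat) == 1L)

  ## ---- stage: simulate / load -------------------------------------
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    design <- readDesignYAML(inp$design)
    mats <- lapply(names(inp$matrices), function(p)
      readExpressionTSV(inp$matrices[[p]]$path,
                        kind = inp$matrices[[p]]$kind, platform = p))
    names(mats) <- names(inp$matrices)
    annotation <- if (!is.null(inp$annotation))
      readAnnotationGTF(inp$annotation) else NULL
    probes <- if (!is.null(inp$probes)) {
      pr <- lapply(names(inp$probes), function(p) {
        g <- readProbesBED(inp$probes[[p]])
        if (is.null(mcols(g)$platform)) mcols(g)$platform <- p
        g
      })
      do.call(c, pr)
    } else NULL
    platforms <- data.frame(
      platform = names(mats),
      kind = vapply(mats, valueKind, ""))
    study <- list(design = design, truth = NULL, annotation = annotation,
                  probes = probes, matrices = mats)
  } else {
    sim <- config$simulate %||% list()
    study <- simulateStudy(
      nGenes = sim$nGenes %||% 20000L,
      probeLevel = isTRUE(sim$probeLevel),
      decoyFraction = sim$decoyFraction %||% 0.05,
      seed = seed)
    platforms <- study$truth@platforms[, c("platform", "kind")]
    writeDesignYAML(study$design, file.path(outdir, "design.yaml"))
    writeTruthYAML(study$truth, file.path(outdir, "truth.yaml"))
  }
  design <- study$design
  mats <- study$matrices
  arrayPlat <- platforms$platform[platforms$kind == "signal"]
  seqPlat <- platforms$platform[platforms$kind == "count"]

  ## ---- stage: map patterns (probe-level runs only) ----------------
  patterns <- NULL; groupings <- list()
  if (!is.null(study$probes) && !is.null(study$annotation)) {
    kept <- filterAmbiguousProbes(study$probes)
    maps <- lapply(arrayPlat, function(p)
      assignTranscriptSets(kept[mcols(kept)$platform == p],
                           study$annotation))
    names(maps) <- arrayPlat
    patterns <- deriveTranscriptPatterns(maps)
    writePatternsTSV(patterns, file.path(outdir, "patterns.tsv"))
    mm <- as.data.frame(patternMembers(patterns))
    groupings <- lapply(arrayPlat, function(p) {
      sub <- mm[mm$platform == p, ]
      stats::setNames(sub$pattern_id, sub$feature_id)
    })
    names(groupings) <- arrayPlat
  }

  ## ---- stage: preprocess ------------------------------------------
  normalized <- list(); detection <- list()
  for (p in platforms$platform) {
    x <- mats[[p]]
    if (valueKind(x) == "signal") {
      nx <- quantileNormalize(x)
      detection[[p]] <- detectionCalls(nx, rule = "pvalue",
                                       pThreshold = thr$pDetection)
    } else {
      nx <- cpmNormalize(x, pseudocount = thr$pseudocount)
      detection[[p]] <- detectionCalls(nx, rule = "cpm",
                                       cpmThreshold = thr$cpmDetection)
    }
    normalized[[p]] <- nx
  }
  collapsed <- lapply(normalized, collapseReplicates, design = design)

  ## ---- stage: signal-domain metrics -------------------------------
  signalMetrics <- list()
  signalMetrics$signalRange <- do.call(rbind,
    lapply(mats, signalRangeSummary))
  bg <- lapply(platforms$platform, function(p) {
    if (p %in% arrayPlat) arrayBackground(mats[[p]])
    else quasiBackground(mats[[p]], design)
  })
  names(bg) <- platforms$platform
  signalMetrics$background <- unlist(bg)
  signalMetrics$signalToBackground <- vapply(platforms$platform,
    function(p) if (bg[[p]] > 0)
      signalToBackground(mats[[p]], bg[[p]], design) else NA_real_,
    numeric(1))
  fid <- lapply(mats, titrationFidelity, design = design,
                threshold = thr$fidelity)
  signalMetrics$titrationFidelity <- vapply(fid, function(z) z@fraction,
                                            numeric(1))
  ## gene-level similarity needs a common index; probe-level runs use
  ## gene-summarized arrays
  simMats <- collapsed
  if (!is.null(study$probes)) {
    for (p in arrayPlat) {
      gmap <- stats::setNames(
        mcols(study$probes)$gene_id[mcols(study$probes)$platform == p],
        mcols(study$probes)$probe_id[mcols(study$probes)$platform == p])
      gmap <- gmap[names(gmap) %in% rownames(normalized[[p]])]
      simMats[[p]] <- collapseReplicates(
        summarizeToLevel(normalized[[p]], gmap), design)
    }
  }
  commonGenes <- alignGenesAcrossPlatforms(lapply(simMats, rownames))
  if (length(commonGenes) >= 2L) {
    signalMetrics$similarity <- lapply(
      stats::setNames(nm = c("AGO", "BMO")),
      function(s) crossPlatformSimilarity(simMats, s, design,
                                          geneIds = commonGenes))
  }

  ## ---- stage: fold-change metrics ----------------------------------
  fcTables <- list(); fcSummary <- list(); compression <- list()
  for (p in platforms$platform) {
    ## linear scale: arrays quantile-normalized signal, counts cpm
    src <- if (!is.null(study$probes) && p %in% arrayPlat)
      simMats[[p]] else collapsed[[p]]
    fct <- buildFoldChangeTable(src, design)
    fcTables[[p]] <- fct
    avg <- averageAbsFC(fct)
    fcSummary[[p]] <- list(
      meanAbsFC = avg$perContrast, overall = avg$overall,
      pctFidelity = 100 * fcTitrationFidelity(
        fct, threshold = thr$fidelity)@fraction)
  }
  if (refPlat %in% names(fcTables)) {
    refLog2 <- log2Ratio(fcTables[[refPlat]])[, "BMO"]
    for (p in setdiff(names(fcTables), refPlat)) {
      oth <- log2Ratio(fcTables[[p]])[, "BMO"]
      genes <- intersect(names(refLog2), names(oth))
      compression[[p]] <- fcCompression(refLog2[genes], oth[genes])
    }
  }

  ## ---- stage: concordance (optional) -------------------------------
  concordance <- NULL
  if (!is.null(config$ct)) {
    ctcfg <- config$ct
    ctTab <- if (!is.null(ctcfg$table)) ctcfg$table else
      readCtTSV(ctcfg$path)
    hk <- ctcfg$housekeeping
    refSample <- ctcfg$referenceSample %||% "AGO"
    contrastSample <- ctcfg$platformSample %||% "BMO"
    ctQc <- qcCt(ctTab, hk)
    pcrFC <- deltaDeltaCt(ctQc, hk, refSample)
    xSigned <- signedFoldChange(pcrFC[, contrastSample])
    calls <- list()
    for (p in names(fcTables)) {
      lr <- log2Ratio(fcTables[[p]])[, contrastSample]
      genes <- intersect(names(xSigned), names(lr))
      if (length(genes) == 0L) next
      ySigned <- signedFoldChange(2^lr[genes])
      v <- classifyConcordance(xSigned[genes], ySigned)
      calls[[p]] <- data.frame(gene = genes, platform = p,
                               x = xSigned[genes], y = ySigned,
                               verdict = as.character(v))
    }
    callDf <- do.call(rbind, calls)
    if (is.null(callDf) || nrow(callDf) == 0L) {
      warning("no genes shared between the Ct table and the platforms")
      concordance <- list(calls = callDf, rate = numeric())
    } else {
      concordance <- list(
        calls = callDf,
        rate = vapply(split(callDf$verdict, callDf$platform),
                      function(z) concordanceRate(z), numeric(1)))
      write.table(callDf, file.path(outdir, "concordance_calls.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  ## ---- stage: report -----------------------------------------------
  accounting <- featureAccounting(mats, detection, patterns)
  write.table(signalMetrics$signalRange,
              file.path(outdir, "signal_range.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(accounting, file.path(outdir, "feature_accounting.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    seed = seed,
    thresholds = thr,
    platforms = platforms$platform,
    nPatterns = if (!is.null(patterns)) length(patterns) else 0L,
    background = as.list(signalMetrics$background),
    signalToBackground = as.list(signalMetrics$signalToBackground),
    titrationFidelity = as.list(signalMetrics$titrationFidelity),
    foldChange = lapply(fcSummary, function(z)
      list(overall = z$overall, pctFidelity = z$pctFidelity)),
    compression = lapply(compression, function(z) z["compression"]),
    concordanceRate = if (!is.null(concordance))
      as.list(concordance$rate) else NULL)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(list(study = study, patterns = patterns,
                 normalized = normalized, collapsed = collapsed,
                 detection = detection, signalMetrics = signalMetrics,
                 foldChange = list(tables = fcTables,
                                   summary = fcSummary,
                                   compression = compression),
                 concordance = concordance, accounting = accounting,
                 summary = summary, outdir = outdir))
}

#' Signed fold-change from a linear ratio
#'
#' Direction is the sign of the log2 ratio; magnitude is the absolute
#' fold-change, so 0.25 becomes -4 and 4 stays +4. The representation
#' [classifyConcordance()] consumes.
#'
#' @param ratio positive linear-scale ratios.
#' @return signed fold-changes (magnitude >= 1).
#' @export
signedFoldChange <- function(ratio) {
  if (any(ratio <= 0)) stop("ratios must be > 0")
  sign(log2(ratio) + .Machine$double.eps) * absoluteFoldChange(ratio)
}

#' Feature accounting across pipeline stages
#'
#' Per platform: total features, non-control features, gene/pattern-level
#' entities, detected entities, and pattern-member features — the
#' bookkeeping that makes stage-to-stage feature loss auditable.
#'
#' @param mats named list of raw [PlatformMatrix-class] objects.
#' @param detection named list of detection-call vectors (as produced by
#'   [detectionCalls()]).
#' @param patterns optional [TranscriptPatternSet-class].
#' @return `data.frame`, one row per platform.
#' @export
featureAccounting <- function(mats, detection = NULL, patterns = NULL) {
  mm <- if (!is.null(patterns))
    as.data.frame(patternMembers(patterns)) else NULL
  rows <- lapply(names(mats), function(p) {
    x <- mats[[p]]
    det <- if (!is.null(detection[[p]])) sum(detection[[p]]) else NA_integer_
    data.frame(
      platform = p,
      total_features = nrow(x),
      noncontrol_features = sum(!isControl(x)),
      detected_features = det,
      pattern_member_features = if (!is.null(mm))
        sum(mm$platform == p) else NA_integer_)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
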
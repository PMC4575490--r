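#' @importFrom stats quantile cor lm coef aggregate
NULL

#' Five-number signal range of the pure samples
#'
#' Minimum, 25th percentile, median, 75th percentile and maximum of
#' non-normalized raw values in the two pure source samples — the basic
#' dynamic-range description of a platform. Percentiles use linear
#' interpolation.
#'
#' @param x a [PlatformMatrix-class] with raw (non-normalized) values.
#' @param samples samples to summarize (default the two pure sources,
#'   `AGO` and `BMO`).
#' @param excludeControls drop negative-control features first (default
#'   `TRUE`).
#' @return `data.frame`: platform, sample, min, q25, median, q75, max,
#'   iqr.
#' @export
signalRangeSummary <- function(x, samples = c("AGO", "BMO"),
                               excludeControls = TRUE) {
  m <- values(x)
  if (excludeControls) m <- m[!isControl(x), , drop = FALSE]
  sm <- colData(x)$sample
  rows <- lapply(samples, function(s) {
    v <- as.vector(m[, sm == s, drop = FALSE])
    q <- quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7)
    data.frame(platform = platformName(x), sample = s,
               min = q[[1]], q25 = q[[2]], median = q[[3]],
               q75 = q[[4]], max = q[[5]], iqr = q[[4]] - q[[2]])
  })
  do.call(rbind, rows)
}

#' Mean background of an array platform
#'
#' The mean value of the designated negative-control features across all
#' columns — the additive noise floor used in the signal-to-background
#' ratio.
#'
#' @param x a [PlatformMatrix-class] with at least one feature flagged in
#'   `rowData(x)$is_control`.
#' @return a single number.
#' @export
arrayBackground <- function(x) {
  ctrl <- isControl(x)
  if (!any(ctrl))
    stop("no negative-control features; supply a background constant ",
         "to signalToBackground() directly")
  mean(values(x)[ctrl, , drop = FALSE])
}

#' Identify noise genes in a count matrix
#'
#' Genes with zero counts in every pure-source column but at least one
#' count in at least one mixture column: counts that cannot derive from
#' either parent RNA, i.e. sequencing noise.
#'
#' @param x a [PlatformMatrix-class] of kind `"count"` (raw counts).
#' @param design a [TitrationDesign-class].
#' @return character vector of noise-gene feature ids.
#' @export
noiseGeneIds <- function(x, design) {
  f <- bmoFraction(design)
  sm <- colData(x)$sample
  pure <- sm %in% names(f)[f %in% c(0, 1)]
  mixed <- sm %in% names(f)[f > 0 & f < 1]
  m <- values(x)
  zeroPure <- rowSums(m[, pure, drop = FALSE]) == 0
  anyMixed <- rowSums(m[, mixed, drop = FALSE]) > 0
  rownames(m)[zeroPure & anyMixed]
}

#' Quasi-background of a sequencing protocol
#'
#' Count data have no physical background, but noise genes (see
#' [noiseGeneIds()]) carry spurious low counts in the mixtures. The
#' quasi-background is the median over the three mixture samples of the
#' 99th percentile of noise-gene raw counts in that sample. With zero
#' noise genes the value is 0, with a warning.
#'
#' @param x raw-count [PlatformMatrix-class].
#' @param design a [TitrationDesign-class].
#' @param allGenes if `TRUE`, take the percentiles over all genes instead
#'   of noise genes only (an alternative reading; default `FALSE`).
#' @return a single number.
#' @export
quasiBackground <- function(x, design, allGenes = FALSE) {
  f <- bmoFraction(design)
  mixedSamples <- names(f)[f > 0 & f < 1]
  ids <- if (allGenes) rownames(x) else noiseGeneIds(x, design)
  if (length(ids) == 0L) {
    warning("no noise genes found; quasi-background is 0")
    return(0)
  }
  sm <- colData(x)$sample
  m <- values(x)[ids, , drop = FALSE]
  p99 <- vapply(mixedSamples, function(s)
    quantile(as.vector(m[, sm == s, drop = FALSE]), 0.99, type = 7,
             names = FALSE), numeric(1))
  median(p99)
}

#' Signal-to-background ratio
#'
#' Mean over the titration samples of each sample's 99th percentile value,
#' divided by the platform's background (array background or sequencing
#' quasi-background). Replicates are averaged first.
#'
#' @param x raw [PlatformMatrix-class].
#' @param background positive background value.
#' @param design a [TitrationDesign-class].
#' @param excludeControls drop negative-control features (default `TRUE`).
#' @return a single number.
#' @export
signalToBackground <- function(x, background, design,
                               excludeControls = TRUE) {
  if (background <= 0) stop("background must be > 0")
  if (excludeControls && any(isControl(x)))
    x <- x[!isControl(x), ]
  cx <- collapseReplicates(x, design)
  p99 <- apply(values(cx), 2L, quantile, 0.99, type = 7, names = FALSE)
  mean(p99) / background
}

#' Fidelity of raw signal to the sample titration
#'
#' Per feature, the Pearson correlation between (replicate-averaged)
#' value and the source-B mixing fraction across the titration samples;
#' reports the fraction of features with `|r|` above the threshold.
#' Zero-variance features have undefined correlation and are excluded
#' from the denominator — they carry no titration information.
#'
#' @param x a [PlatformMatrix-class] (raw values by default in the
#'   pipeline; pass log2 values via `useLog2`).
#' @param design a [TitrationDesign-class] with >= 3 distinct fractions.
#' @param threshold absolute-correlation cutoff (default 0.5).
#' @param useLog2 correlate `log2(value + 1)` instead of raw (default
#'   `FALSE`).
#' @param excludeControls drop negative-control features (default `TRUE`).
#' @return a [FidelityResult-class].
#' @export
titrationFidelity <- function(x, design, threshold = 0.5,
                              useLog2 = FALSE, excludeControls = TRUE) {
  f <- bmoFraction(design)
  if (length(unique(f)) < 3L) stop("need >= 3 distinct fractions")
  if (excludeControls && any(isControl(x)))
    x <- x[!isControl(x), ]
  cx <- collapseReplicates(x, design)
  m <- values(cx)[, sampleLabels(design), drop = FALSE]
  if (useLog2) m <- log2(m + 1)
  sds <- apply(m, 1L, stats::sd)
  r <- rep(NA_real_, nrow(m))
  ok <- sds > 0
  r[ok] <- as.vector(cor(t(m[ok, , drop = FALSE]), f))
  names(r) <- rownames(m)
  new("FidelityResult", correlations = r,
      fraction = mean(abs(r[ok]) > threshold),
      threshold = threshold, nEvaluable = sum(ok))
}

#' Cross-platform similarity of one sample
#'
#' Spearman rank correlation between every pair of platforms on a common
#' gene index for the chosen sample (replicates averaged). Symmetric with
#' unit diagonal.
#'
#' @param matrices named list of gene-level [PlatformMatrix-class]
#'   objects.
#' @param sample sample label to compare.
#' @param design a [TitrationDesign-class].
#' @param geneIds optional common gene ids; default: the intersection of
#'   the matrices' rownames ([alignGenesAcrossPlatforms()]).
#' @return platform x platform correlation matrix.
#' @export
crossPlatformSimilarity <- function(matrices, sample, design,
                                    geneIds = NULL) {
  if (is.null(geneIds))
    geneIds <- alignGenesAcrossPlatforms(lapply(matrices, rownames))
  if (length(geneIds) < 2L) stop("fewer than 2 common genes")
  v <- vapply(matrices, function(x) {
    cx <- collapseReplicates(x, design)
    values(cx)[geneIds, sample]
  }, numeric(length(geneIds)))
  s <- cor(v, method = "spearman")
  diag(s) <- 1
  s
}
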
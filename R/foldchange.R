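#' Absolute fold-change
#'
#' Maps a positive expression ratio to a magnitude >= 1 by taking the
#' reciprocal of ratios below 1, so up- and down-regulation are directly
#' comparable: `abs_fc(r) = r` if `r >= 1`, else `1 / r`.
#'
#' @param ratio positive numeric vector.
#' @return numeric vector >= 1.
#' @examples
#' absoluteFoldChange(c(2, 0.25, 1))  # 2, 4, 1
#' @export
absoluteFoldChange <- function(ratio) {
  if (any(ratio <= 0)) stop("ratios must be > 0")
  ifelse(ratio >= 1, ratio, 1 / ratio)
}

#' Build the per-gene fold-change table for the titration contrasts
#'
#' Ratios of every mixture (and pure source B) sample against the pure
#' source-A sample, computed on the linear scale of a normalized,
#' replicate-collapsed matrix: cpm (with pseudocount) for count
#' platforms, normalized signal for arrays. Array values are floored at a
#' small positive constant so logs stay finite; flooring events are
#' counted in attribute `"floored"`. `log2`-kind matrices are
#' back-transformed (`2^v - 1`) first.
#'
#' @param x a [PlatformMatrix-class], normalized and replicate-collapsed
#'   (see [collapseReplicates()]); must contain the `AGO` column.
#' @param design a [TitrationDesign-class].
#' @param detectedOnly drop genes failing detection (default `FALSE`).
#' @param detected named logical vector of detection calls (required when
#'   `detectedOnly = TRUE`).
#' @param floor lower clamp applied before ratioing (default 1e-6).
#' @return a [FoldChangeTable-class].
#' @export
buildFoldChangeTable <- function(x, design, detectedOnly = FALSE,
                                 detected = NULL, floor = 1e-6) {
  m <- values(x)
  sm <- colData(x)$sample
  if (any(duplicated(sm)))
    stop("collapse replicates before building fold-changes")
  colnames(m) <- sm
  ref <- "AGO"
  if (!ref %in% sm) stop("AGO column missing")
  if (any(isControl(x))) m <- m[!isControl(x), , drop = FALSE]
  if (valueKind(x) == "log2") m <- 2^m - 1
  if (detectedOnly) {
    if (is.null(detected)) stop("detectedOnly needs detection calls")
    keep <- rownames(m)[detected[rownames(m)] %in% TRUE]
    m <- m[keep, , drop = FALSE]
  }
  nFloored <- sum(m < floor)
  m[m < floor] <- floor
  f <- bmoFraction(design)
  contrasts <- sampleLabels(design)[f > 0]
  ratio <- m[, contrasts, drop = FALSE] / m[, ref]
  fct <- new("FoldChangeTable", platform = platformName(x),
             contrasts = contrasts,
             contrastFraction = unname(f[contrasts]),
             ratio = ratio, log2ratio = log2(ratio),
             absFC = absoluteFoldChange(ratio))
  attr(fct, "floored") <- nFloored
  fct
}

#' Average absolute fold-change per contrast and overall
#'
#' Arithmetic mean of absolute fold-changes at each titration contrast
#' over a gene subset; the overall platform value is the mean of the
#' per-contrast means.
#'
#' @param fct a [FoldChangeTable-class].
#' @param geneSubset optional gene ids; default all genes in the table.
#' @return `list(perContrast = named numeric, overall = numeric)`.
#' @export
averageAbsFC <- function(fct, geneSubset = NULL) {
  a <- absFoldChange(fct)
  if (!is.null(geneSubset)) {
    bad <- setdiff(geneSubset, rownames(a))
    if (length(bad)) stop("subset gene(s) absent from table")
    a <- a[geneSubset, , drop = FALSE]
  }
  if (nrow(a) == 0L) stop("empty gene subset")
  per <- colMeans(a)
  list(perContrast = per, overall = mean(per))
}

#' Fidelity of absolute fold-change to the titration
#'
#' Per gene, the Pearson correlation between absolute fold-change and the
#' contrast's source-B fraction along the four titration contrasts;
#' reports the fraction of genes with `r` strictly greater than the
#' (positive, one-sided) threshold. Zero-variance genes are excluded
#' from the denominator.
#'
#' @param fct a [FoldChangeTable-class] with all 4 contrasts.
#' @param threshold one-sided correlation cutoff (default +0.5).
#' @param xVar `"fraction"` (default; correlate against the mixture
#'   fractions) or `"ordinal"` (contrast index 1-4).
#' @return a [FidelityResult-class] (here `fraction` counts `r >
#'   threshold`, not `|r|`).
#' @export
fcTitrationFidelity <- function(fct, threshold = 0.5,
                                xVar = c("fraction", "ordinal")) {
  xVar <- match.arg(xVar)
  a <- absFoldChange(fct)
  if (ncol(a) < 4L) stop("all 4 titration contrasts are required")
  xv <- if (xVar == "fraction") fct@contrastFraction else
    seq_len(ncol(a))
  sds <- apply(a, 1L, stats::sd)
  r <- rep(NA_real_, nrow(a))
  ok <- sds > 0
  r[ok] <- as.vector(cor(t(a[ok, , drop = FALSE]), xv))
  names(r) <- rownames(a)
  new("FidelityResult", correlations = r,
      fraction = mean(r[ok] > threshold),
      threshold = threshold, nEvaluable = sum(ok))
}

#' Fold-change enhancement
#'
#' Relative percent gain in overall average absolute fold-change when
#' moving from a baseline feature set to a refined one (detected-only, or
#' transcript-pattern-restricted): `(refined - baseline) / baseline *
#' 100`.
#'
#' @param baseline,refined overall average absolute fold-changes;
#'   baseline must be > 0.
#' @return percent, a single number.
#' @examples
#' fcEnhancement(5.42, 8.88)  # ~64
#' @export
fcEnhancement <- function(baseline, refined) {
  if (baseline <= 0) stop("baseline must be > 0")
  (refined - baseline) / baseline * 100
}

#' Cross-platform fold-change compression
#'
#' Ordinary least-squares fit of one platform's log2 ratios on a
#' reference platform's (`other = a + b * reference`, free intercept)
#' over a common gene set. The slope `b` measures how much of the
#' reference's fold-change the platform reproduces; compression is
#' `(1 - b) * 100` percent.
#'
#' @param referenceLog2,otherLog2 paired finite log2 ratios (>= 3 pairs,
#'   reference not constant).
#' @return `list(slope, r.squared, compression)`.
#' @export
fcCompression <- function(referenceLog2, otherLog2) {
  ok <- is.finite(referenceLog2) & is.finite(otherLog2)
  xr <- referenceLog2[ok]; yo <- otherLog2[ok]
  if (length(xr) < 3L) stop("need >= 3 finite pairs")
  if (stats::sd(xr) == 0) stop("reference log2 ratios have zero variance")
  fit <- lm(yo ~ xr)
  b <- unname(coef(fit)[2])
  # R^2 of a simple OLS fit is the squared correlation
  list(slope = b, r.squared = cor(xr, yo)^2,
       compression = (1 - b) * 100)
}
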
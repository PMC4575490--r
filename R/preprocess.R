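#' Quantile-normalize an array signal matrix
#'
#' Forces every column onto the common distribution given by the
#' across-column mean of sorted values; within-column ties receive the
#' mean of the reference values spanned by their ranks. Idempotent: a
#' second application is a no-op.
#'
#' @param x a [PlatformMatrix-class] of kind `"signal"`, or a plain
#'   numeric matrix, with at least 2 columns and no missing values.
#' @return the normalized object, same class as the input (a
#'   `PlatformMatrix` keeps its metadata, kind stays `"signal"`).
#' @export
quantileNormalize <- function(x) {
  m <- if (is(x, "PlatformMatrix")) values(x) else as.matrix(x)
  if (is(x, "PlatformMatrix") && valueKind(x) != "signal")
    stop("quantile normalization applies to kind 'signal'")
  if (ncol(m) < 2L) stop("need >= 2 columns")
  if (anyNA(m)) stop("missing values are not allowed")
  ref <- rowMeans(apply(m, 2L, sort))
  norm <- apply(m, 2L, function(v) {
    o <- order(v)
    grp <- cumsum(!duplicated(v[o]))  # tie groups in sorted order
    out <- numeric(length(v))
    out[o] <- stats::ave(ref, grp)   # ties: mean over their rank span
    out
  })
  dimnames(norm) <- dimnames(m)
  if (is(x, "PlatformMatrix")) {
    assay(x, "values") <- norm
    x
  } else norm
}

#' Counts-per-million normalization with pseudocount
#'
#' Adds the pseudocount to every entry first, then scales each column by
#' its incremented library size to one million:
#' `cpm = (count + k) / sum(count + k) * 1e6`. With `k >= 1` no entry is
#' zero, so downstream ratios and logs stay finite. Incrementing before
#' computing the library size is the default; `librarySize = "raw"` uses
#' the un-incremented column sums instead.
#'
#' @param x a [PlatformMatrix-class] of kind `"count"`, or a count matrix.
#' @param pseudocount non-negative count added to every entry (default 1).
#' @param librarySize `"incremented"` (default) or `"raw"`.
#' @return cpm values, same class as input (kind becomes `"cpm"`).
#' @export
cpmNormalize <- function(x, pseudocount = 1,
                         librarySize = c("incremented", "raw")) {
  librarySize <- match.arg(librarySize)
  m <- if (is(x, "PlatformMatrix")) values(x) else as.matrix(x)
  if (is(x, "PlatformMatrix") && valueKind(x) != "count")
    stop("cpm normalization applies to kind 'count'")
  if (length(m) == 0L) stop("empty matrix")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  inc <- m + pseudocount
  lib <- if (librarySize == "incremented") colSums(inc) else colSums(m)
  if (any(lib <= 0)) stop("zero library size; use pseudocount >= 1")
  cpm <- sweep(inc, 2, lib, "/") * 1e6
  if (is(x, "PlatformMatrix")) {
    out <- PlatformMatrix(cpm, kind = "cpm", platform = platformName(x),
                          sample = colData(x)$sample,
                          replicate = colData(x)$replicate,
                          isControl = isControl(x))
    out
  } else cpm
}

#' Detection calls per feature and per group
#'
#' Sequencing rule: a feature is detected iff its cpm exceeds 0.25
#' (strictly) in at least one column. Array rule: detected iff its
#' detection p-value is below the threshold in at least one column. At
#' gene/pattern level an entity is detected iff *any* member feature is
#' detected in *any* sample.
#'
#' @param x a [PlatformMatrix-class]. For `rule = "cpm"` the values must
#'   be cpm; for `rule = "pvalue"` a `detection_p` assay must be present.
#' @param rule `"cpm"` or `"pvalue"`.
#' @param cpmThreshold strict cpm cutoff (default 0.25).
#' @param pThreshold strict p-value cutoff (default 0.05).
#' @param grouping optional named character vector `feature -> group`; when
#'   supplied a second element `group` is returned with the any-member
#'   rule applied.
#' @return named logical vector per feature, or
#'   `list(feature = ..., group = ...)` when `grouping` is given.
#' @export
detectionCalls <- function(x, rule = c("cpm", "pvalue"),
                           cpmThreshold = 0.25, pThreshold = 0.05,
                           grouping = NULL) {
  rule <- match.arg(rule)
  if (rule == "cpm") {
    if (valueKind(x) != "cpm")
      stop("cpm detection rule needs a cpm matrix; run cpmNormalize()")
    det <- apply(values(x) > cpmThreshold, 1L, any)
  } else {
    if (!"detection_p" %in% names(assays(x)))
      stop("p-value detection rule needs a 'detection_p' assay")
    det <- apply(assay(x, "detection_p") < pThreshold, 1L, any)
  }
  names(det) <- rownames(x)
  if (is.null(grouping)) return(det)
  feats <- intersect(names(det), names(grouping))
  grp <- tapply(det[feats], grouping[feats], any)
  grp <- setNames(as.logical(grp), names(grp))
  list(feature = det, group = grp[!is.na(grp)])
}

#' One-step Tukey biweight location estimate
#'
#' The robust average used to summarize member features to pattern/gene
#' level: with median `m` and (unscaled) median absolute deviation `s`,
#' each value gets `u = (x - m) / (c * s + epsilon)` and weight
#' `(1 - u^2)^2` when `|u| < 1`, zero otherwise; the estimate is the
#' weighted mean. Lies within the input range and is permutation
#' invariant; a single value is returned as itself.
#'
#' @param x numeric vector with at least one finite value.
#' @param c tuning constant (default 5).
#' @param epsilon guard against zero spread (default 1e-4).
#' @return the biweight location, a single number.
#' @examples
#' tukeyBiweight(c(1, 1, 1, 10))  # pulled far less than the mean 3.25
#' @export
tukeyBiweight <- function(x, c = 5, epsilon = 1e-4) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("need at least one finite value")
  if (length(x) == 1L) return(x)
  m <- median(x)
  s <- median(abs(x - m))
  u <- (x - m) / (c * s + epsilon)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  sum(w * x) / sum(w)
}

#' Summarize features to pattern or gene level
#'
#' Per group and column, the Tukey biweight of member values on the
#' `log2(value + 1)` scale; the result is reported on that log2 scale
#' (kind `"log2"`). Summarizing on the log scale keeps the noise roughly
#' symmetric for both signal and count platforms. Groups with no member
#' present in the matrix are absent from the output.
#'
#' @param x a [PlatformMatrix-class] (linear-scale values).
#' @param grouping named character vector `feature id -> group id`; every
#'   named feature must be present in the matrix.
#' @param c,epsilon biweight parameters, see [tukeyBiweight()].
#' @return a `PlatformMatrix` of kind `"log2"` at the grouped level.
#' @export
summarizeToLevel <- function(x, grouping, c = 5, epsilon = 1e-4) {
  unknown <- setdiff(names(grouping), rownames(x))
  if (length(unknown))
    stop("grouping references unknown feature(s): ",
         paste(utils::head(unknown, 3), collapse = ", "))
  m <- log2(values(x)[names(grouping), , drop = FALSE] + 1)
  groups <- sort(unique(grouping))
  out <- matrix(NA_real_, length(groups), ncol(m),
                dimnames = list(groups, colnames(m)))
  idx <- split(seq_along(grouping), grouping)
  for (g in groups)
    out[g, ] <- apply(m[idx[[g]], , drop = FALSE], 2L, tukeyBiweight,
                      c = c, epsilon = epsilon)
  PlatformMatrix(out, kind = "log2", platform = platformName(x),
                 sample = colData(x)$sample,
                 replicate = colData(x)$replicate)
}

#' Average replicate columns into one column per sample
#'
#' Replicates are averaged (arithmetic mean, on the current scale) before
#' every downstream metric, so platforms with different replicate counts
#' contribute sample-level quantities alike.
#'
#' @param x a [PlatformMatrix-class].
#' @param design optional [TitrationDesign-class]; its sample order is
#'   used for the output columns.
#' @return a `PlatformMatrix` with one column per sample.
#' @export
collapseReplicates <- function(x, design = NULL) {
  sm <- colData(x)$sample
  samples <- if (!is.null(design)) sampleLabels(design) else unique(sm)
  if (!all(samples %in% sm))
    stop("sample(s) with zero replicate columns: ",
         paste(setdiff(samples, sm), collapse = ", "))
  m <- values(x)
  out <- vapply(samples, function(s)
    rowMeans(m[, sm == s, drop = FALSE]), numeric(nrow(m)))
  if (nrow(m) == 1L) out <- matrix(out, 1L, dimnames = list(rownames(m), samples))
  colnames(out) <- samples
  kind <- valueKind(x)
  if (kind == "count") kind <- "signal"  # means of counts are not integers
  pm <- PlatformMatrix(out, kind = kind, platform = platformName(x),
                       sample = samples,
                       replicate = rep(1L, length(samples)),
                       isControl = isControl(x))
  pm
}
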
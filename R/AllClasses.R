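#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays rowData colData
NULL

#' Titration mixture design
#'
#' Describes a two-source RNA titration series: ordered sample labels, the
#' proportion of source B (bone-marrow-like, "BMO") in each mixture, and the
#' number of technical replicates run per sample on each platform.
#'
#' @slot samples ordered character vector of sample labels, from pure source A
#'   to pure source B.
#' @slot bmoFraction numeric vector, same length as `samples`; proportion of
#'   source B in each sample. Strictly increasing, endpoints exactly 0 and 1.
#' @slot replicates integer matrix, samples x platforms; replicate counts,
#'   all >= 1.
#'
#' @seealso [canonicalTitrationDesign()], [mixingFraction()]
#' @export
setClass("TitrationDesign",
  representation(
    samples    = "character",
    bmoFraction = "numeric",
    replicates  = "matrix"
  )
)

setValidity("TitrationDesign", function(object) {
  msg <- character()
  f <- object@bmoFraction
  if (length(f) != length(object@samples))
    msg <- c(msg, "bmoFraction and samples lengths differ")
  if (length(f) >= 2) {
    if (any(diff(f) <= 0))
      msg <- c(msg, "bmoFraction must be strictly increasing")
    if (f[1] != 0 || f[length(f)] != 1)
      msg <- c(msg, "bmoFraction endpoints must be exactly 0 and 1")
  }
  r <- object@replicates
  if (nrow(r) != length(object@samples))
    msg <- c(msg, "replicates must have one row per sample")
  if (any(r < 1) || any(r != round(r)))
    msg <- c(msg, "every sample needs >= 1 replicate on every platform")
  if (length(msg)) msg else TRUE
})

#' @describeIn TitrationDesign-class construct a design from its parts.
#' @param samples,bmoFraction,replicates see slots.
#' @export
TitrationDesign <- function(samples, bmoFraction, replicates) {
  if (is.null(dim(replicates)))
    replicates <- matrix(as.integer(replicates), nrow = length(samples),
                         ncol = 1, dimnames = list(samples, "platform1"))
  storage.mode(replicates) <- "integer"
  rownames(replicates) <- samples
  new("TitrationDesign", samples = samples,
      bmoFraction = as.numeric(bmoFraction), replicates = replicates)
}

#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))
#' @export
setGeneric("bmoFraction", function(x, ...) standardGeneric("bmoFraction"))
#' @export
setGeneric("replicateCounts", function(x) standardGeneric("replicateCounts"))

#' @describeIn TitrationDesign-class sample labels in titration order.
#' @param x a `TitrationDesign`.
#' @export
setMethod("sampleLabels", "TitrationDesign", function(x) x@samples)

#' @describeIn TitrationDesign-class named source-B proportions.
#' @export
setMethod("bmoFraction", "TitrationDesign",
          function(x, ...) stats::setNames(x@bmoFraction, x@samples))

#' @describeIn TitrationDesign-class samples x platforms replicate matrix.
#' @export
setMethod("replicateCounts", "TitrationDesign", function(x) x@replicates)

setMethod("show", "TitrationDesign", function(object) {
  cat("TitrationDesign with", length(object@samples), "samples and",
      ncol(object@replicates), "platform(s)\n")
  df <- data.frame(sample = object@samples,
                   bmo_fraction = object@bmoFraction,
                   object@replicates, check.names = FALSE)
  print(df, row.names = FALSE)
})

#' Expression matrix for one platform
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying one platform's
#' feature x replicate-column values together with the value kind, the
#' platform label, optional per-feature detection p-values (assay
#' `"detection_p"`) and negative-control flags (`rowData(x)$is_control`).
#' Column data holds the `sample` each replicate column belongs to and the
#' `replicate` index.
#'
#' @slot kind one of `"signal"`, `"count"`, `"cpm"`, `"log2"`.
#' @slot platform platform label.
#' @export
setClass("PlatformMatrix",
  contains = "SummarizedExperiment",
  representation(kind = "character", platform = "character")
)

setValidity("PlatformMatrix", function(object) {
  msg <- character()
  if (!object@kind %in% c("signal", "count", "cpm", "log2"))
    msg <- c(msg, "kind must be one of signal/count/cpm/log2")
  if (!"values" %in% names(assays(object)))
    msg <- c(msg, "assay 'values' is required")
  v <- assay(object, "values")
  if (anyDuplicated(rownames(v)))
    msg <- c(msg, "duplicate feature ids")
  if (object@kind == "count") {
    if (any(v < 0) || any(v != round(v)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  if (object@kind == "cpm" && ncol(v) > 0) {
    cs <- colSums(v)
    if (any(abs(cs - 1e6) > 1e-6 * 1e6))
      msg <- c(msg, "cpm columns must each sum to 1e6")
  }
  if (!all(c("sample", "replicate") %in% names(colData(object))))
    msg <- c(msg, "colData must carry 'sample' and 'replicate'")
  if (length(msg)) msg else TRUE
})

#' @describeIn PlatformMatrix-class construct from a plain matrix.
#' @param values numeric matrix, features x replicate columns, rownames =
#'   feature ids.
#' @param kind value kind (`"signal"`, `"count"`, `"cpm"`, `"log2"`).
#' @param platform platform label.
#' @param sample character vector mapping each column to its sample.
#' @param replicate integer replicate index per column (default: running
#'   index within sample).
#' @param detectionP optional matrix of per-feature per-column detection
#'   p-values.
#' @param isControl optional logical vector flagging negative-control
#'   features.
#' @export
PlatformMatrix <- function(values, kind, platform, sample,
                           replicate = NULL, detectionP = NULL,
                           isControl = NULL) {
  values <- as.matrix(values)
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(sample), sample, FUN = seq_along)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    colnames(values) <- paste0(sample, "_r", replicate)
  assays <- list(values = values)
  if (!is.null(detectionP)) {
    detectionP <- as.matrix(detectionP)
    dimnames(detectionP) <- dimnames(values)
    assays$detection_p <- detectionP
  }
  if (is.null(isControl)) isControl <- rep(FALSE, nrow(values))
  se <- SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(is_control = isControl, row.names = rownames(values)),
    colData = DataFrame(sample = sample, replicate = as.integer(replicate),
                        row.names = colnames(values))
  )
  new("PlatformMatrix", se, kind = kind, platform = platform)
}

#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))
#' @export
setGeneric("platformName", function(x) standardGeneric("platformName"))
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @export
setGeneric("isControl", function(x) standardGeneric("isControl"))

#' @describeIn PlatformMatrix-class the value kind.
#' @param x a `PlatformMatrix`.
#' @export
setMethod("valueKind", "PlatformMatrix", function(x) x@kind)
#' @describeIn PlatformMatrix-class the platform label.
#' @export
setMethod("platformName", "PlatformMatrix", function(x) x@platform)
#' @describeIn PlatformMatrix-class the feature x column value matrix.
#' @export
setMethod("values", "PlatformMatrix", function(x) assay(x, "values"))
#' @describeIn PlatformMatrix-class negative-control flags.
#' @export
setMethod("isControl", "PlatformMatrix",
          function(x) rowData(x)$is_control)

setMethod("show", "PlatformMatrix", function(object) {
  cat("PlatformMatrix [", object@platform, "] kind=", object@kind, ": ",
      nrow(object), " features x ", ncol(object), " columns (",
      length(unique(colData(object)$sample)), " samples)\n", sep = "")
})

#' Cross-platform common transcript patterns
#'
#' The central comparison construct: within a gene, a *transcript pattern* is
#' an exact set of transcript identifiers jointly targeted by at least one
#' feature on every required platform. A gene may contribute several
#' patterns; pattern identity is exact set equality, never subset.
#'
#' @slot patterns `DataFrame` with columns `pattern_id`, `gene_id`,
#'   `transcripts` (a `CharacterList` of sorted transcript ids).
#' @slot members `DataFrame` with columns `platform`, `feature_id`,
#'   `pattern_id`, `gene_id`: the features summarized under each pattern.
#' @export
setClass("TranscriptPatternSet",
  representation(patterns = "DataFrame", members = "DataFrame")
)

setValidity("TranscriptPatternSet", function(object) {
  msg <- character()
  p <- object@patterns
  need <- c("pattern_id", "gene_id", "transcripts")
  if (!all(need %in% names(p)))
    msg <- c(msg, "patterns must have pattern_id, gene_id, transcripts")
  else {
    if (anyDuplicated(p$pattern_id)) msg <- c(msg, "duplicate pattern ids")
    if (any(lengths(p$transcripts) == 0))
      msg <- c(msg, "empty transcript set")
    key <- paste(p$gene_id, vapply(p$transcripts,
                 function(z) paste(sort(z), collapse = ";"), ""))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (gene, transcript-set) pattern")
  }
  m <- object@members
  if (!all(c("platform", "feature_id", "pattern_id") %in% names(m)))
    msg <- c(msg, "members must have platform, feature_id, pattern_id")
  else if (nrow(m)) {
    # within a gene and platform a feature belongs to exactly one pattern
    if (anyDuplicated(paste(m$platform, m$feature_id)))
      msg <- c(msg, "a feature may belong to at most one pattern")
  }
  if (length(msg)) msg else TRUE
})

#' @export
setGeneric("patternTable", function(x) standardGeneric("patternTable"))
#' @export
setGeneric("patternMembers", function(x) standardGeneric("patternMembers"))

#' @describeIn TranscriptPatternSet-class pattern-level table.
#' @param x a `TranscriptPatternSet`.
#' @export
setMethod("patternTable", "TranscriptPatternSet", function(x) x@patterns)
#' @describeIn TranscriptPatternSet-class per-platform feature membership.
#' @export
setMethod("patternMembers", "TranscriptPatternSet", function(x) x@members)

setMethod("show", "TranscriptPatternSet", function(object) {
  cat("TranscriptPatternSet:", nrow(object@patterns), "patterns in",
      length(unique(object@patterns$gene_id)), "genes;",
      nrow(object@members), "member features on",
      length(unique(object@members$platform)), "platform(s)\n")
})

#' @describeIn TranscriptPatternSet-class number of patterns.
#' @export
setMethod("length", "TranscriptPatternSet",
          function(x) nrow(x@patterns))

#' Per-gene fold changes for the titration contrasts
#'
#' Holds, for one platform and a set of genes (or patterns), the ratio, the
#' log2 ratio and the absolute fold-change of each of the four titration
#' contrasts against the pure source-A sample.
#'
#' @slot platform platform label.
#' @slot contrasts character, contrast labels (mixture sample names).
#' @slot contrastFraction numeric, source-B fraction of each contrast sample.
#' @slot ratio,log2ratio,absFC numeric gene x contrast matrices.
#' @export
setClass("FoldChangeTable",
  representation(platform = "character", contrasts = "character",
                 contrastFraction = "numeric",
                 ratio = "matrix", log2ratio = "matrix", absFC = "matrix")
)

setValidity("FoldChangeTable", function(object) {
  msg <- character()
  d <- dim(object@ratio)
  if (!identical(d, dim(object@log2ratio)) ||
      !identical(d, dim(object@absFC)))
    msg <- c(msg, "ratio/log2ratio/absFC dimensions differ")
  if (length(object@contrasts) != ncol(object@ratio))
    msg <- c(msg, "one column per contrast required")
  if (any(object@absFC < 1 - 1e-12))
    msg <- c(msg, "absolute fold-change must be >= 1")
  if (any(!is.finite(object@log2ratio)))
    msg <- c(msg, "log2 ratios must be finite")
  if (length(msg)) msg else TRUE
})

#' @export
setGeneric("absFoldChange", function(x) standardGeneric("absFoldChange"))
#' @export
setGeneric("log2Ratio", function(x) standardGeneric("log2Ratio"))

#' @describeIn FoldChangeTable-class gene x contrast absolute fold-changes.
#' @param x a `FoldChangeTable`.
#' @export
setMethod("absFoldChange", "FoldChangeTable", function(x) x@absFC)
#' @describeIn FoldChangeTable-class gene x contrast log2 ratios.
#' @export
setMethod("log2Ratio", "FoldChangeTable", function(x) x@log2ratio)

setMethod("show", "FoldChangeTable", function(object) {
  cat("FoldChangeTable [", object@platform, "]: ", nrow(object@ratio),
      " genes x ", length(object@contrasts), " contrasts (",
      paste(object@contrasts, collapse = ", "), ")\n", sep = "")
})

#' Titration fidelity of a platform's features
#'
#' Per-feature Pearson correlation between value and the source-B mixing
#' fraction across the titration samples, and the fraction of evaluable
#' features whose |r| exceeds a threshold.
#'
#' @slot correlations named numeric; `NA` marks undefined (zero-variance)
#'   features, which are excluded from the fraction's denominator.
#' @slot fraction fraction of evaluable features with |r| > threshold.
#' @slot threshold the threshold used.
#' @slot nEvaluable number of features entering the denominator.
#' @export
setClass("FidelityResult",
  representation(correlations = "numeric", fraction = "numeric",
                 threshold = "numeric", nEvaluable = "integer")
)

setValidity("FidelityResult", function(object) {
  msg <- character()
  r <- object@correlations
  if (any(abs(r[!is.na(r)]) > 1 + 1e-8))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (!is.na(object@fraction) &&
      (object@fraction < 0 || object@fraction > 1))
    msg <- c(msg, "fraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FidelityResult", function(object) {
  cat(sprintf(
    "FidelityResult: %.1f%% of %d evaluable features with |r| > %g\n",
    100 * object@fraction, object@nEvaluable, object@threshold))
})
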
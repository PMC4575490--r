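#' Quality-control a Ct table
#'
#' Applies the two qPCR reliability rules at the gene-sample cell level:
#' a cell fails if more than `failFraction` of its replicate Ct values
#' exceed `maxCt` (non-amplification), or if the coefficient of variation
#' of its replicate Ct values exceeds `maxCv` (unreliable replication).
#' Genes that lose any required sample are excluded from downstream
#' analysis entirely; the housekeeping gene failing QC in any sample is
#' an error, because nothing can be normalized without it.
#'
#' @param ct `data.frame` with columns `gene`, `sample`, `replicate`,
#'   `ct`.
#' @param housekeeping housekeeping gene id.
#' @param maxCt cycle cutoff marking failed amplification (default 40).
#' @param maxCv coefficient-of-variation cutoff (default 0.30).
#' @param failFraction fraction of replicates over `maxCt` beyond which
#'   the cell is dropped — strictly more than (default 0.5).
#' @param requiredSamples samples every retained gene must keep (default:
#'   all samples present).
#' @return the filtered Ct `data.frame`; attribute `"droppedCells"`
#'   lists the failing gene-sample cells.
#' @export
qcCt <- function(ct, housekeeping, maxCt = 40, maxCv = 0.30,
                 failFraction = 0.5,
                 requiredSamples = unique(ct$sample)) {
  stopifnot(all(c("gene", "sample", "ct") %in% names(ct)))
  key <- paste(ct$gene, ct$sample, sep = "\r")
  failHigh <- tapply(ct$ct, key, function(z) mean(z > maxCt) > failFraction)
  cv <- tapply(ct$ct, key, function(z)
    if (length(z) > 1L) stats::sd(z) / mean(z) else 0)
  bad <- names(failHigh)[failHigh | cv[names(failHigh)] > maxCv]
  keep <- !(key %in% bad)
  out <- ct[keep, , drop = FALSE]
  badGene <- unique(vapply(strsplit(bad, "\r", fixed = TRUE), `[`, "", 1L))
  # genes losing any required sample drop out entirely
  haveAll <- tapply(out$sample, out$gene,
                    function(s) all(requiredSamples %in% s))
  lost <- names(haveAll)[!haveAll]
  if (housekeeping %in% c(lost, badGene))
    stop("housekeeping gene '", housekeeping, "' fails QC")
  out <- out[!out$gene %in% lost, , drop = FALSE]
  attr(out, "droppedCells") <- bad
  out
}

#' Delta-delta Ct fold-changes
#'
#' Relative quantification against a housekeeping gene and a reference
#' sample: replicate Ct values are averaged per gene and sample, then
#' `dCt = Ct_gene - Ct_housekeeping` within each sample,
#' `ddCt = dCt_sample - dCt_reference`, and the fold-change is
#' `2^(-ddCt)`. By construction the reference sample's fold-change is 1.
#'
#' @param ct QC-passed Ct `data.frame` (`gene`, `sample`, `replicate`,
#'   `ct`).
#' @param housekeeping housekeeping gene id, present in every sample.
#' @param referenceSample the sample everything is expressed relative to.
#' @return numeric matrix, genes (housekeeping excluded) x samples, of
#'   fold-changes.
#' @export
deltaDeltaCt <- function(ct, housekeeping, referenceSample) {
  if (!referenceSample %in% ct$sample)
    stop("reference sample '", referenceSample, "' missing")
  if (!housekeeping %in% ct$gene)
    stop("housekeeping gene '", housekeeping, "' missing")
  mean_ct <- aggregate(ct ~ gene + sample, ct, mean)
  wide <- tapply(mean_ct$ct, list(mean_ct$gene, mean_ct$sample), identity)
  hk <- wide[housekeeping, ]
  dct <- sweep(wide, 2, hk)
  ddct <- dct - dct[, referenceSample]
  fc <- 2^(-ddct)
  fc[setdiff(rownames(fc), housekeeping), , drop = FALSE]
}

#' Classify fold-change agreement between a platform and a reference
#'
#' Four-way verdict for one gene's comparison of a reference fold-change
#' X (e.g. qRT-PCR) with a platform fold-change Y, both given as signed
#' fold-changes (sign = direction of the log2 ratio, magnitude =
#' absolute fold-change). Same direction: magnitude ratio
#' `|X|/|Y| >= 2` is `compressed`, `<= 0.5` is `overestimate`, in
#' between is `concordant`. Different directions: `opposite` when either
#' magnitude exceeds 2; when both magnitudes are within (0.5, 2] neither
#' assay claims a meaningful change, so the comparison is `concordant`.
#'
#' @param x,y signed fold-changes (equal-length vectors); zero magnitude
#'   is an error.
#' @return factor with levels `compressed`, `opposite`, `overestimate`,
#'   `concordant`.
#' @examples
#' classifyConcordance(c(4, 2, 3), c(1.5, 5, -3))
#' @export
classifyConcordance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (any(x == 0) || any(y == 0)) stop("zero fold-change magnitude")
  mx <- abs(x); my <- abs(y)
  sameDir <- sign(x) == sign(y)
  ratio <- mx / my
  verdict <- ifelse(sameDir,
    ifelse(ratio >= 2, "compressed",
           ifelse(ratio <= 0.5, "overestimate", "concordant")),
    ifelse(mx > 2 | my > 2, "opposite", "concordant"))
  factor(verdict,
         levels = c("compressed", "opposite", "overestimate",
                    "concordant"))
}

#' Concordance rate
#'
#' Percent of comparisons called `concordant` or `overestimate` — the
#' calls in which the platform reproduces at least the reference's
#' magnitude in the right direction.
#'
#' @param calls factor of verdicts from [classifyConcordance()].
#' @return percent, a single number.
#' @export
concordanceRate <- function(calls) {
  if (length(calls) == 0L) stop("no calls")
  100 * mean(calls %in% c("concordant", "overestimate"))
}

#' Genes whose PCR amplicon falls inside a common transcript pattern
#'
#' A qPCR comparator gene joins the pattern-level comparison only when
#' its amplicon interval maps — by the same full-containment rule used
#' for probes — to one of that gene's derived transcript patterns, so
#' the PCR assay measures the same transcript set the platforms do.
#'
#' @param amplicons `GRanges` of amplicon intervals with metadata columns
#'   `gene_id` and (optionally) `probe_id`/assay id.
#' @param patterns a [TranscriptPatternSet-class].
#' @param annotation exon `GRanges`.
#' @return character vector of retained gene ids.
#' @export
ampliconPatternOverlap <- function(amplicons, patterns, annotation) {
  if (is.null(mcols(amplicons)$probe_id))
    mcols(amplicons)$probe_id <- paste0("amplicon",
                                        seq_along(amplicons))
  amap <- assignTranscriptSets(amplicons, annotation)
  if (nrow(amap) == 0L) return(character())
  pt <- patternTable(patterns)
  pkey <- paste(pt$gene_id, vapply(pt$transcripts, function(z)
    paste(sort(z), collapse = ";"), ""), sep = "\t")
  akey <- paste(amap$gene_id, amap$transcript_set, sep = "\t")
  sort(unique(amap$gene_id[akey %in% pkey]))
}
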
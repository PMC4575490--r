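#' @importFrom GenomicRanges findOverlaps reduce
#' @importFrom S4Vectors queryHits subjectHits split
NULL

#' Drop ambiguously aligned probes
#'
#' Probes whose alignment to the genome is multiple or partial report
#' confounded signal and are omitted from all downstream analysis; only
#' uniquely and fully aligned probes are retained.
#'
#' @param probes a `GRanges` (or `data.frame`) with metadata columns
#'   `probe_id` and `class`, the alignment class per probe
#'   (`"unique_full"`, `"multiple"` or `"partial"`).
#' @return the retained subset, with an attribute `"removed"` tabulating
#'   removals per alignment class.
#' @export
filterAmbiguousProbes <- function(probes) {
  cls <- if (is(probes, "GRanges")) mcols(probes)$class else probes$class
  if (is.null(cls)) stop("probes must carry an alignment 'class' column")
  keep <- cls == "unique_full"
  removed <- table(factor(cls[!keep], levels = c("multiple", "partial")))
  out <- probes[keep, ]
  if (is(probes, "GRanges")) out <- probes[keep]
  attr(out, "removed") <- removed
  if (sum(removed) > 0)
    message("filterAmbiguousProbes: removed ", removed[["multiple"]],
            " multiple- and ", removed[["partial"]],
            " partial-alignment probes; retained ", sum(keep))
  out
}

#' Map probes to the transcript sets they target
#'
#' A transcript is targeted by a probe if and only if *every* genomic
#' interval of the probe is fully contained within the transcript's exon
#' union — containment, not mere overlap: a probe partially hanging off an
#' exon reports mixed exonic/intronic signal. Probes targeting no
#' transcript are dropped; probes whose transcripts span more than one
#' gene are cross-gene ambiguous and dropped too.
#'
#' @param probes filtered probe `GRanges` with metadata columns `probe_id`
#'   and (optionally) `platform`; multi-interval probes share a
#'   `probe_id` and count a transcript only when all their intervals are
#'   contained.
#' @param annotation exon `GRanges` with `gene_id`, `transcript_id`.
#' @return `data.frame` with one row per retained probe: `probe_id`,
#'   `platform`, `gene_id`, `transcript_set` (sorted transcript ids joined
#'   by `";"`). Attribute `"dropped"` counts probes lost to empty or
#'   cross-gene sets.
#' @export
assignTranscriptSets <- function(probes, annotation) {
  pc <- unique(as.character(seqnames(probes)))
  ac <- unique(as.character(seqnames(annotation)))
  if (!all(pc %in% ac))
    stop("annotation is missing chromosome(s): ",
         paste(setdiff(pc, ac), collapse = ", "))
  txOf <- setNames(mcols(annotation)$gene_id,
                   mcols(annotation)$transcript_id)
  txOf <- txOf[!duplicated(names(txOf))]
  exUnion <- reduce(S4Vectors::split(annotation,
                                     mcols(annotation)$transcript_id))
  flat <- unlist(exUnion)
  txFlat <- rep(names(exUnion), lengths(exUnion))
  fo <- findOverlaps(probes, flat, type = "within", ignore.strand = TRUE)
  pid <- mcols(probes)$probe_id
  plat <- mcols(probes)$platform
  if (is.null(plat)) plat <- rep(NA_character_, length(probes))
  nInt <- table(pid)  # intervals per probe
  hitTx <- data.frame(probe = pid[queryHits(fo)],
                      tx = txFlat[subjectHits(fo)],
                      interval = queryHits(fo))
  # a probe targets tx iff all of its intervals are within that tx's exons
  hitTx <- unique(hitTx)
  cnt <- if (nrow(hitTx)) {
    agg <- stats::aggregate(interval ~ probe + tx, hitTx,
                            function(z) length(unique(z)))
    agg[agg$interval == as.integer(nInt[agg$probe]), ]
  } else hitTx[0, ]
  dropped <- c(empty = 0L, cross_gene = 0L)
  keepRows <- list()
  if (nrow(cnt)) {
    bySet <- split(cnt$tx, cnt$probe)
    firstIdx <- match(names(bySet), pid)
    genes <- lapply(bySet, function(tx) unique(unname(txOf[tx])))
    multi <- lengths(genes) > 1L
    dropped["cross_gene"] <- sum(multi)
    ok <- !multi
    keepRows <- data.frame(
      probe_id = names(bySet)[ok],
      platform = plat[firstIdx][ok],
      gene_id = unlist(genes[ok]),
      transcript_set = vapply(bySet[ok], function(z)
        paste(sort(unique(z)), collapse = ";"), ""),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    keepRows <- data.frame(probe_id = character(), platform = character(),
                           gene_id = character(),
                           transcript_set = character())
  }
  dropped["empty"] <- length(unique(pid)) - nrow(keepRows) -
    dropped["cross_gene"]
  attr(keepRows, "dropped") <- dropped
  keepRows
}

#' Derive cross-platform common transcript patterns
#'
#' A (gene, transcript-set) pair becomes a *transcript pattern* if and
#' only if, on every required platform, at least one feature maps to
#' exactly that transcript set. Pattern identity is exact set equality —
#' two different common sets of the same gene stay two separate patterns.
#' A gene may therefore contribute several patterns, each summarized
#' separately downstream.
#'
#' @param maps named list (one element per platform) of probe-to-set maps
#'   as returned by [assignTranscriptSets()].
#' @param requiredPlatforms platforms a set must be present on (default:
#'   all supplied); at least 2.
#' @return a [TranscriptPatternSet-class], sorted by gene then pattern id.
#' @export
deriveTranscriptPatterns <- function(maps,
                                     requiredPlatforms = names(maps)) {
  if (length(requiredPlatforms) < 2L)
    stop("at least 2 platforms are required")
  missing <- setdiff(requiredPlatforms, names(maps))
  if (length(missing))
    stop("required platform(s) absent from input: ",
         paste(missing, collapse = ", "))
  keyOf <- function(df) unique(paste(df$gene_id, df$transcript_set,
                                     sep = "\t"))
  common <- Reduce(intersect, lapply(maps[requiredPlatforms], keyOf))
  parts <- strsplit(common, "\t", fixed = TRUE)
  genes <- vapply(parts, `[`, "", 1L)
  sets <- vapply(parts, `[`, "", 2L)
  ord <- order(genes, sets)
  genes <- genes[ord]; sets <- sets[ord]; common <- common[ord]
  pid <- sprintf("%s:P%02d", genes,
                 stats::ave(seq_along(genes), genes, FUN = seq_along))
  patterns <- DataFrame(
    pattern_id = pid, gene_id = genes,
    transcripts = IRanges::CharacterList(strsplit(sets, ";", fixed = TRUE)))
  memb <- lapply(names(maps), function(p) {
    df <- maps[[p]]
    key <- paste(df$gene_id, df$transcript_set, sep = "\t")
    hit <- match(key, common)
    ok <- !is.na(hit)
    data.frame(platform = rep(p, sum(ok)), feature_id = df$probe_id[ok],
               pattern_id = pid[hit[ok]], gene_id = df$gene_id[ok],
               stringsAsFactors = FALSE)
  })
  memb <- do.call(rbind, memb)
  new("TranscriptPatternSet", patterns = patterns,
      members = DataFrame(memb))
}

#' Map annotation exons onto derived patterns
#'
#' An exon maps to a pattern if and only if the set of transcripts
#' containing that exon equals the pattern's transcript set exactly; exons
#' matching no pattern are left unmapped. This is how sequencing exons
#' join the pattern-level comparison: by set equality alone, without
#' requiring the exon itself to be probe-targeted.
#'
#' @param annotation exon `GRanges`; exon identity is `exon_id` when
#'   present, otherwise the genomic interval.
#' @param patterns a [TranscriptPatternSet-class].
#' @return `data.frame` with columns `exon_id`, `gene_id`, `pattern_id`
#'   for the mapped exons only.
#' @export
mapExonsToPatterns <- function(annotation, patterns) {
  mc <- mcols(annotation)
  exKey <- if (!is.null(mc$exon_id)) mc$exon_id else
    paste0(seqnames(annotation), ":", start(annotation), "-",
           end(annotation))
  df <- unique(data.frame(exon = exKey, gene = mc$gene_id,
                          tx = mc$transcript_id))
  setOf <- vapply(split(df$tx, df$exon),
                  function(z) paste(sort(unique(z)), collapse = ";"), "")
  geneOf <- df$gene[match(names(setOf), df$exon)]
  pt <- patternTable(patterns)
  pkey <- paste(pt$gene_id, vapply(pt$transcripts, function(z)
    paste(sort(z), collapse = ";"), ""), sep = "\t")
  hit <- match(paste(geneOf, setOf, sep = "\t"), pkey)
  ok <- !is.na(hit)
  data.frame(exon_id = names(setOf)[ok], gene_id = geneOf[ok],
             pattern_id = pt$pattern_id[hit[ok]],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genes common to all platforms
#'
#' The exact intersection of per-platform gene identifier lists — the
#' gene-symbol-aligned comparison level.
#'
#' @param geneLists named list of character vectors, one per platform.
#' @return sorted character vector of common gene ids.
#' @export
alignGenesAcrossPlatforms <- function(geneLists) {
  stopifnot(length(geneLists) >= 1L)
  sort(Reduce(intersect, lapply(geneLists, unique)))
}
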
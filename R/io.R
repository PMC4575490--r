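#' @importFrom utils read.delim write.table head
#' @importFrom rtracklayer import export
NULL

#' Read / write annotation as GTF
#'
#' Thin wrappers over [rtracklayer::import()]/`export()` keeping only
#' exon records with `gene_id`, `transcript_id`, `exon_id`.
#'
#' @param path file path.
#' @param annotation exon `GRanges`.
#' @return `readAnnotationGTF`: an exon `GRanges`.
#' @export
readAnnotationGTF <- function(path) {
  gr <- import(path, format = "gtf")
  gr <- gr[mcols(gr)$type == "exon"]
  mcols(gr) <- mcols(gr)[, intersect(
    c("type", "gene_id", "transcript_id", "exon_id"),
    names(mcols(gr)))]
  gr
}

#' @rdname readAnnotationGTF
#' @export
writeAnnotationGTF <- function(annotation, path) {
  export(annotation, path, format = "gtf")
  invisible(path)
}

#' Read / write probe intervals as BED6 plus a class table
#'
#' Probe coordinates travel as BED6 (name = probe id, score unused); the
#' alignment metadata (platform, alignment class, contaminant) that BED
#' cannot carry goes in a companion TSV written next to it
#' (`<path>.meta.tsv`).
#'
#' @param probes probe `GRanges` from [simulateProbes()].
#' @param path BED file path.
#' @return `readProbesBED`: probe `GRanges` with metadata restored (class
#'   defaults to `"unique_full"` when no companion table exists).
#' @export
writeProbesBED <- function(probes, path) {
  bed <- probes
  names(bed) <- mcols(bed)$probe_id
  mcols(bed) <- NULL
  export(bed, path, format = "bed")
  meta <- as.data.frame(mcols(probes))
  write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProbesBED
#' @export
readProbesBED <- function(path) {
  gr <- import(path, format = "bed")
  ids <- if (!is.null(names(gr))) names(gr) else mcols(gr)$name
  mcols(gr)$name <- NULL
  mcols(gr)$probe_id <- ids
  metaPath <- paste0(path, ".meta.tsv")
  if (file.exists(metaPath)) {
    meta <- read.delim(metaPath, stringsAsFactors = FALSE)
    i <- match(mcols(gr)$probe_id, meta$probe_id)
    for (colnm in setdiff(names(meta), "probe_id"))
      mcols(gr)[[colnm]] <- meta[[colnm]][i]
  } else {
    mcols(gr)$class <- "unique_full"
  }
  gr
}

#' Read / write an expression matrix as TSV
#'
#' Column 1 is `feature_id`, then one column per sample-replicate named
#' `<sample>_r<replicate>`; an optional `is_control` column flags
#' negative controls.
#'
#' @param x a [PlatformMatrix-class].
#' @param path TSV path.
#' @param kind,platform value kind and platform label for reading.
#' @return `readExpressionTSV`: a `PlatformMatrix`.
#' @export
writeExpressionTSV <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), values(x),
                   is_control = isControl(x), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpressionTSV
#' @export
readExpressionTSV <- function(path, kind, platform) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ctrl <- if ("is_control" %in% names(df)) df$is_control else NULL
  df$is_control <- NULL
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  sample <- sub("_r[0-9]+$", "", colnames(m))
  replicate <- as.integer(sub("^.*_r", "", colnames(m)))
  PlatformMatrix(m, kind = kind, platform = platform, sample = sample,
                 replicate = replicate, isControl = ctrl)
}

#' Read / write the titration design as YAML
#'
#' @param design a [TitrationDesign-class].
#' @param path YAML path.
#' @return `readDesignYAML`: a `TitrationDesign`.
#' @export
writeDesignYAML <- function(design, path) {
  reps <- replicateCounts(design)
  yaml::write_yaml(list(
    samples = sampleLabels(design),
    bmo_fraction = unname(bmoFraction(design)),
    platforms = colnames(reps),
    replicates = lapply(seq_len(ncol(reps)), function(j) unname(reps[, j]))
  ), path)
  invisible(path)
}

#' @rdname writeDesignYAML
#' @export
readDesignYAML <- function(path) {
  y <- yaml::read_yaml(path)
  reps <- do.call(cbind, lapply(y$replicates, as.integer))
  dimnames(reps) <- list(y$samples, y$platforms)
  TitrationDesign(y$samples, as.numeric(y$bmo_fraction), reps)
}

#' Write the synthetic ground truth as YAML
#'
#' @param truth a [SyntheticTruth-class].
#' @param path YAML path.
#' @export
writeTruthYAML <- function(truth, path) {
  yaml::write_yaml(list(
    seed = truth@seed,
    genes = truth@genes,
    baseline_a = truth@baselineA,
    baseline_b = truth@baselineB,
    noise_gene = truth@noiseGene,
    platforms = as.list(truth@platforms)
  ), path)
  invisible(path)
}

#' Write derived transcript patterns as TSV
#'
#' One row per member feature: `pattern_id`, `gene_id`, `transcript_ids`
#' (semicolon-joined), `platform`, `feature_id`.
#'
#' @param patterns a [TranscriptPatternSet-class].
#' @param path TSV path.
#' @export
writePatternsTSV <- function(patterns, path) {
  pt <- patternTable(patterns)
  tx <- vapply(pt$transcripts, function(z) paste(sort(z), collapse = ";"),
               "")
  names(tx) <- pt$pattern_id
  m <- as.data.frame(patternMembers(patterns))
  out <- data.frame(pattern_id = m$pattern_id, gene_id = m$gene_id,
                    transcript_ids = tx[m$pattern_id],
                    platform = m$platform, feature_id = m$feature_id)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pattern select regions as BED
#'
#' Exports the exon intervals whose transcript set equals a derived
#' pattern's set — the genomic regions a feature must fall in to report
#' that pattern. BED name is `<pattern_id>|<exon_id>`.
#'
#' @param patterns a [TranscriptPatternSet-class].
#' @param annotation exon `GRanges` the patterns were derived from.
#' @param path BED file path.
#' @export
writePatternRegionsBED <- function(patterns, annotation, path) {
  em <- mapExonsToPatterns(annotation, patterns)
  mc <- mcols(annotation)
  exKey <- if (!is.null(mc$exon_id)) mc$exon_id else
    paste0(seqnames(annotation), ":", start(annotation), "-",
           end(annotation))
  idx <- match(em$exon_id, exKey)
  bed <- annotation[idx]
  mcols(bed) <- NULL
  names(bed) <- paste0(em$pattern_id, "|", em$exon_id)
  export(bed, path, format = "bed")
  invisible(path)
}

#' Read a Ct table from TSV
#'
#' Expects columns `gene`, `sample`, `replicate`, `ct`.
#'
#' @param path TSV path.
#' @return a `data.frame`.
#' @examples
#' ct <- readCtTSV(system.file("extdata", "example_ct.tsv",
#'                             package = "titrationBench"))
#' fc <- deltaDeltaCt(qcCt(ct, "GUSB"), "GUSB", "AGO")
#' round(fc[, "BMO"], 2)
#' @export
readCtTSV <- function(path) {
  ct <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "sample", "ct") %in% names(ct)))
  ct
}
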
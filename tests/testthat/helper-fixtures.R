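suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

## ---- hand-built gene with five transcripts and known pattern geometry ----
## Regions (100 bp each) and the transcript subset sharing each:
##   R1 1000-1099  t001,t003,t004,t005   <- "pattern B" analogue
##   R2 2000-2099  t002
##   R3 3000-3099  all five              <- "pattern E" analogue
##   R4 4000-4099  t001,t002
##   R5 5000-5099  t003
fig1Annotation <- function() {
  regions <- data.frame(
    id = paste0("R", 1:5),
    start = c(1000, 2000, 3000, 4000, 5000),
    end   = c(1099, 2099, 3099, 4099, 5099))
  membership <- list(
    R1 = c("t001", "t003", "t004", "t005"),
    R2 = "t002",
    R3 = c("t001", "t002", "t003", "t004", "t005"),
    R4 = c("t001", "t002"),
    R5 = "t003")
  rows <- do.call(rbind, lapply(regions$id, function(r) {
    data.frame(start = regions$start[regions$id == r],
               end = regions$end[regions$id == r],
               transcript_id = membership[[r]], exon_id = paste0("TBP.", r))
  }))
  gr <- GRanges("chr1", IRanges(rows$start, rows$end), strand = "+")
  mcols(gr)$type <- "exon"
  mcols(gr)$gene_id <- "TBP"
  mcols(gr)$transcript_id <- rows$transcript_id
  mcols(gr)$exon_id <- rows$exon_id
  gr
}

## probes per platform: every platform targets R1 and R3; the non-common
## regions R2, R4, R5 are each targeted by a single platform only, so only
## the R1 and R3 transcript sets can become cross-platform patterns.
fig1Probes <- function() {
  place <- rbind(
    data.frame(platform = "arrayA", region = c("R1", "R3", "R4")),
    data.frame(platform = "arrayB", region = c("R1", "R1", "R3", "R2")),
    data.frame(platform = "arrayC", region = c("R1", "R3", "R5")),
    data.frame(platform = "arrayD", region = c("R1", "R3")))
  startOf <- c(R1 = 1010, R2 = 2010, R3 = 3010, R4 = 4010, R5 = 5010)
  st <- startOf[place$region] + 5 * stats::ave(
    seq_len(nrow(place)), place$platform, place$region, FUN = seq_along)
  gr <- GRanges("chr1", IRanges(st, st + 24), strand = "+")
  mcols(gr)$probe_id <- paste0(place$platform, ":p",
                               seq_len(nrow(place)))
  mcols(gr)$platform <- place$platform
  mcols(gr)$class <- "unique_full"
  gr
}

## ---- brute-force oracles -------------------------------------------------

## containment of every probe interval in the transcript's exon union,
## by explicit loops
bfAssignTranscriptSets <- function(probes, annotation) {
  pid <- mcols(probes)$probe_id
  txAll <- unique(mcols(annotation)$transcript_id)
  geneOfTx <- setNames(mcols(annotation)$gene_id,
                       mcols(annotation)$transcript_id)
  geneOfTx <- geneOfTx[!duplicated(names(geneOfTx))]
  out <- list()
  for (p in unique(pid)) {
    iv <- probes[pid == p]
    hits <- character()
    for (tx in txAll) {
      ex <- annotation[mcols(annotation)$transcript_id == tx]
      contained <- vapply(seq_along(iv), function(i) {
        any(as.character(seqnames(ex)) == as.character(seqnames(iv))[i] &
            start(ex) <= start(iv)[i] & end(ex) >= end(iv)[i])
      }, logical(1))
      if (all(contained)) hits <- c(hits, tx)
    }
    if (length(hits) == 0L) next
    genes <- unique(unname(geneOfTx[hits]))
    if (length(genes) > 1L) next
    out[[p]] <- data.frame(
      probe_id = p, platform = mcols(iv)$platform[1], gene_id = genes,
      transcript_set = paste(sort(hits), collapse = ";"))
  }
  df <- do.call(rbind, out)
  if (is.null(df))
    df <- data.frame(probe_id = character(), platform = character(),
                     gene_id = character(), transcript_set = character())
  rownames(df) <- NULL
  df
}

## exhaustive intersection over all (gene, transcript-set) pairs
bfPatternKeys <- function(maps, required = names(maps)) {
  cand <- unique(do.call(rbind, lapply(maps[required], function(df)
    df[, c("gene_id", "transcript_set")])))
  if (nrow(cand) == 0L) return(character())
  ok <- vapply(seq_len(nrow(cand)), function(i) {
    all(vapply(maps[required], function(df)
      any(df$gene_id == cand$gene_id[i] &
          df$transcript_set == cand$transcript_set[i]), logical(1)))
  }, logical(1))
  sort(paste(cand$gene_id[ok], cand$transcript_set[ok], sep = "\t"))
}

patternKeys <- function(patterns) {
  pt <- patternTable(patterns)
  sort(paste(pt$gene_id, vapply(pt$transcripts, function(z)
    paste(sort(z), collapse = ";"), ""), sep = "\t"))
}

## literal transcription of the four-way concordance rules
bfClassify <- function(x, y) {
  sameDir <- sign(x) == sign(y)
  r <- abs(x) / abs(y)
  if (sameDir) {
    if (r >= 2) return("compressed")
    if (r <= 0.5) return("overestimate")
    return("concordant")
  }
  if (abs(x) > 2 || abs(y) > 2) return("opposite")
  "concordant"
}

## direct-formula oracles for the summarization/normalization operations
bfBiweight <- function(x, cc = 5, eps = 1e-4) {
  m <- median(x)
  s <- median(abs(x - m))
  tot <- 0; wtot <- 0
  for (xi in x) {
    u <- (xi - m) / (cc * s + eps)
    w <- if (abs(u) < 1) (1 - u^2)^2 else 0
    tot <- tot + w * xi; wtot <- wtot + w
  }
  tot / wtot
}

bfQuantileNorm <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    rk <- rank(m[, j], ties.method = "min")
    for (i in seq_len(nrow(m))) {
      span <- which(sort(m[, j]) == m[i, j])
      out[i, j] <- mean(ref[span])
    }
  }
  out
}

bfCpm <- function(m, k = 1) {
  inc <- m + k
  for (j in seq_len(ncol(m))) inc[, j] <- inc[, j] / sum(m[, j] + k) * 1e6
  inc
}

bfDdct <- function(ct, hk, refSample) {
  genes <- setdiff(unique(ct$gene), hk)
  samples <- unique(ct$sample)
  meanCt <- function(g, s) mean(ct$ct[ct$gene == g & ct$sample == s])
  out <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
  for (g in genes) for (s in samples) {
    dct <- meanCt(g, s) - meanCt(hk, s)
    dctRef <- meanCt(g, refSample) - meanCt(hk, refSample)
    out[g, s] <- 2^(-(dct - dctRef))
  }
  out
}

## small helper: platform table for bespoke simulation scenarios
makePlatforms <- function(platform, kind = "signal", compression = 1,
                          noise = 0, background = 0, gain = 1,
                          libSize = NA) {
  n <- length(platform)
  data.frame(platform = platform, kind = rep_len(kind, n),
             compression = rep_len(compression, n),
             noise = rep_len(noise, n),
             background = rep_len(background, n),
             gain = rep_len(gain, n), libSize = rep_len(libSize, n),
             probeLength = NA, probesPerGene = NA, placement = NA,
             stringsAsFactors = FALSE)
}
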
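#' @importFrom GenomicRanges GRanges mcols mcols<- seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom stats rnorm runif rpois rnbinom median pnorm setNames
NULL

#' Ground truth of a synthetic titration study
#'
#' Per-gene baseline abundances in the two pure RNA sources, noise-gene
#' flags, and the per-platform generative parameters (compression exponent,
#' noise scale, background, gain, library size). A compression exponent of
#' 1 means no compression. Noise genes have baseline 0 in both pure
#' sources and acquire only occasional low counts in mixture samples.
#'
#' @slot genes gene identifiers.
#' @slot baselineA,baselineB positive (or zero, for noise genes) abundances
#'   in pure source A / source B, arbitrary units.
#' @slot noiseGene logical flags.
#' @slot platforms platform parameter `data.frame` (see
#'   [defaultPlatforms()]).
#' @slot seed the seed that fully determines all downstream realizations.
#' @export
setClass("SyntheticTruth",
  representation(genes = "character", baselineA = "numeric",
                 baselineB = "numeric", noiseGene = "logical",
                 platforms = "data.frame", seed = "numeric")
)

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  n <- length(object@genes)
  if (length(object@baselineA) != n || length(object@baselineB) != n ||
      length(object@noiseGene) != n)
    msg <- c(msg, "per-gene slots must all have one entry per gene")
  if (any(object@baselineA < 0) || any(object@baselineB < 0))
    msg <- c(msg, "baselines must be non-negative")
  if (any(object@baselineA[object@noiseGene] != 0) ||
      any(object@baselineB[object@noiseGene] != 0))
    msg <- c(msg, "noise genes must have zero baseline in both sources")
  p <- object@platforms
  if (any(p$compression <= 0 | p$compression > 1))
    msg <- c(msg, "compression exponents must lie in (0, 1]")
  if (any(p$noise < 0)) msg <- c(msg, "noise scales must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@genes), "genes (",
      sum(object@noiseGene), "noise genes ) x",
      nrow(object@platforms), "platforms; seed", object@seed, "\n")
})

#' @export
setGeneric("noiseGenes", function(x, ...) standardGeneric("noiseGenes"))

#' @describeIn SyntheticTruth-class ids of the planted noise genes.
#' @param x a `SyntheticTruth`.
#' @export
setMethod("noiseGenes", "SyntheticTruth",
          function(x, ...) x@genes[x@noiseGene])

#' Simulate a transcript annotation
#'
#' Generates a gene/transcript/exon annotation with the interval geometry
#' needed downstream: each gene owns a set of exon "slots" along the
#' chromosome and each transcript includes a subset of them, so different
#' slots are shared by different transcript subsets — exactly the geometry
#' that lets a probe distinguish transcript subsets of one gene.
#'
#' Exons of one transcript are non-overlapping and sorted; every transcript
#' belongs to exactly one gene; slots shared between transcripts have
#' identical coordinates, so "the set of transcripts containing this exon"
#' is well defined per interval.
#'
#' @param nGenes number of genes.
#' @param transcriptsPerGene integer range `c(lo, hi)` of transcripts per
#'   gene.
#' @param exonsPerTranscript integer range of exons per transcript.
#' @param exonWidth integer range of exon widths (bp), must be positive.
#' @param seed integer seed; identical seeds give identical annotations.
#' @return a [GenomicRanges::GRanges] of exons with metadata columns
#'   `gene_id`, `transcript_id`, `exon_id` and `type = "exon"`.
#' @export
simulateAnnotation <- function(nGenes, transcriptsPerGene = c(2L, 5L),
                               exonsPerTranscript = c(2L, 8L),
                               exonWidth = c(150L, 400L), seed = 1L) {
  if (nGenes < 1) stop("nGenes must be positive")
  if (any(transcriptsPerGene < 1) || any(exonsPerTranscript < 1))
    stop("transcript and exon counts must be positive")
  if (any(exonWidth < 1)) stop("exon widths must be positive")
  withr::with_seed(seed, {
    genesPerChrom <- 500L
    out <- vector("list", nGenes)
    cursor <- 1L; chrom <- 1L
    for (g in seq_len(nGenes)) {
      if (g > 1L && (g - 1L) %% genesPerChrom == 0L) {
        chrom <- chrom + 1L; cursor <- 1L
      }
      gid <- sprintf("gene%05d", g)
      nSlots <- max(exonsPerTranscript) + 2L
      widths <- sample(seq(exonWidth[1], exonWidth[2]), nSlots,
                       replace = TRUE)
      gaps <- sample(200:2000, nSlots, replace = TRUE)
      starts <- cursor + cumsum(gaps) +
        c(0L, cumsum(widths))[seq_len(nSlots)]
      ends <- starts + widths - 1L
      cursor <- ends[nSlots] + sample(5000:20000, 1L)
      str <- sample(c("+", "-"), 1L)
      nTx <- sample(seq(transcriptsPerGene[1], transcriptsPerGene[2]), 1L)
      txRows <- vector("list", nTx)
      for (t in seq_len(nTx)) {
        k <- sample(seq(exonsPerTranscript[1],
                        min(exonsPerTranscript[2], nSlots)), 1L)
        slots <- sort(sample.int(nSlots, k))
        txRows[[t]] <- data.frame(
          chrom = paste0("chr", chrom),
          start = starts[slots], end = ends[slots], strand = str,
          gene_id = gid,
          transcript_id = sprintf("%s.t%02d", gid, t),
          exon_id = sprintf("%s.e%02d", gid, slots),
          stringsAsFactors = FALSE)
      }
      out[[g]] <- do.call(rbind, txRows)
    }
    df <- do.call(rbind, out)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
    mcols(gr)$type <- "exon"
    mcols(gr)$gene_id <- df$gene_id
    mcols(gr)$transcript_id <- df$transcript_id
    mcols(gr)$exon_id <- df$exon_id
    gr
  })
}

#' Simulate per-platform probe intervals
#'
#' Places probes of each array-like platform fully inside exons of their
#' source gene, with either 3'-biased or whole-transcript placement. A
#' configurable fraction of decoy probes is emitted flagged as
#' multi-mapping or partially aligned (and carrying a cross-hybridizing
#' contaminant gene), to exercise the ambiguity filter downstream.
#'
#' @param annotation exon `GRanges` from [simulateAnnotation()].
#' @param platforms platform `data.frame` ([defaultPlatforms()]); only
#'   `kind == "signal"` rows receive probes.
#' @param decoyFraction probability that a probe is emitted as a decoy.
#' @param seed integer seed.
#' @return a `GRanges` of probe intervals with metadata columns
#'   `probe_id`, `platform`, `gene_id`, `class` (`"unique_full"`,
#'   `"multiple"` or `"partial"`) and `contaminant` (decoys only).
#' @export
simulateProbes <- function(annotation, platforms = defaultPlatforms(),
                           decoyFraction = 0.05, seed = 1L) {
  if (decoyFraction < 0 || decoyFraction > 1)
    stop("decoyFraction must lie in [0, 1]")
  arr <- platforms[platforms$kind == "signal", , drop = FALSE]
  ex <- as.data.frame(annotation)
  # unique exon slots per gene (slots shared by transcripts collapse)
  slots <- unique(ex[, c("seqnames", "start", "end", "strand",
                         "gene_id", "exon_id")])
  geneIds <- unique(slots$gene_id)
  withr::with_seed(seed, {
    res <- vector("list", nrow(arr))
    for (i in seq_len(nrow(arr))) {
      p <- arr[i, ]
      eligible <- slots[slots$end - slots$start + 1L >= p$probeLength, ]
      if (nrow(eligible) == 0L)
        stop("no exon is long enough for probe length ", p$probeLength)
      rows <- vector("list", length(geneIds))
      for (gi in seq_along(geneIds)) {
        g <- geneIds[gi]
        cand <- eligible[eligible$gene_id == g, , drop = FALSE]
        if (nrow(cand) == 0L) next
        # 3'-biased platforms prefer downstream slots (strand-aware)
        w <- rep(1, nrow(cand))
        if (identical(p$placement, "threeprime")) {
          rank3 <- if (cand$strand[1] == "-")
            rank(-cand$start) else rank(cand$start)
          w <- rank3^2
        }
        idx <- sample.int(nrow(cand), p$probesPerGene, replace = TRUE,
                          prob = w)
        st <- vapply(idx, function(j) {
          cand$start[j] +
            sample.int(cand$end[j] - cand$start[j] - p$probeLength + 2L,
                       1L) - 1L
        }, numeric(1))
        decoy <- runif(length(idx)) < decoyFraction
        cls <- ifelse(decoy,
                      sample(c("multiple", "partial"), length(idx),
                             replace = TRUE),
                      "unique_full")
        contam <- rep(NA_character_, length(idx))
        if (any(decoy) && length(geneIds) > 1L)
          contam[decoy] <- sample(setdiff(geneIds, g), sum(decoy),
                                  replace = TRUE)
        rows[[gi]] <- data.frame(
          chrom = as.character(cand$seqnames[idx]), start = st,
          end = st + p$probeLength - 1L,
          strand = as.character(cand$strand[idx]),
          probe_id = sprintf("%s:%s:p%02d", p$platform, g,
                             seq_along(idx)),
          platform = p$platform, gene_id = g, class = cls,
          contaminant = contam, stringsAsFactors = FALSE)
      }
      res[[i]] <- do.call(rbind, rows)
    }
    df <- do.call(rbind, res)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
    mcols(gr)$probe_id <- df$probe_id
    mcols(gr)$platform <- df$platform
    mcols(gr)$gene_id <- df$gene_id
    mcols(gr)$class <- df$class
    mcols(gr)$contaminant <- df$contaminant
    gr
  })
}

#' Simulate the per-gene ground truth
#'
#' Draws log-normal baseline abundances for pure source A, applies a
#' differential-expression effect to a fraction of genes to obtain source
#' B, and plants a small fraction of noise genes with zero baseline in
#' both sources.
#'
#' @param genes gene identifiers (character), or a single integer giving
#'   the number of genes (ids are then generated to match
#'   [simulateAnnotation()] naming).
#' @param platforms platform parameter `data.frame`.
#' @param pDiff fraction of (non-noise) genes differential between the two
#'   sources. The two sources emulate very different RNA pools, so half
#'   the transcriptome shifting is the intended regime.
#' @param effectSd standard deviation of the differential log2 effect.
#' @param pNoiseGene fraction of genes planted as noise genes (default 4 %,
#'   matching a "less than 5 % of genes" regime).
#' @param baselineLog2Mean,baselineLog2Sd mean/sd of log2 baseline
#'   abundance in source A.
#' @param seed integer seed.
#' @return a [SyntheticTruth-class].
#' @export
simulateTruth <- function(genes, platforms = defaultPlatforms(),
                          pDiff = 0.5, effectSd = 2, pNoiseGene = 0.04,
                          baselineLog2Mean = 6, baselineLog2Sd = 2.2,
                          seed = 1L) {
  if (pDiff < 0 || pDiff > 1 || pNoiseGene < 0 || pNoiseGene > 1)
    stop("pDiff and pNoiseGene must lie in [0, 1]")
  if (effectSd < 0 || baselineLog2Sd < 0)
    stop("scale parameters must be non-negative")
  if (is.numeric(genes) && length(genes) == 1L)
    genes <- sprintf("gene%05d", seq_len(genes))
  n <- length(genes)
  withr::with_seed(seed, {
    eA <- 2^rnorm(n, baselineLog2Mean, baselineLog2Sd)
    delta <- ifelse(runif(n) < pDiff, rnorm(n, 0, effectSd), 0)
    eB <- eA * 2^delta
    noise <- runif(n) < pNoiseGene
    eA[noise] <- 0; eB[noise] <- 0
    new("SyntheticTruth", genes = genes, baselineA = eA, baselineB = eB,
        noiseGene = noise, platforms = platforms, seed = as.numeric(seed))
  })
}

#' Simulate per-platform expression matrices for the titration
#'
#' The expected pre-noise abundance of gene *g* in sample *s* is the
#' mixture `f * eB + (1 - f) * eA` with `f` the source-B fraction of *s*.
#' Array-like platforms emit
#' `signal = background + gain * abundance^c * exp(noise * z)` with
#' standard-normal `z`, plus negative-control features at background;
#' sequencing-like platforms draw negative-binomial counts with mean
#' proportional to `abundance^c` times the column's library size
#' (dispersion = the platform `noise` parameter; 0 gives Poisson). Noise
#' genes emit occasional low counts (1-12) in mixture columns only and are
#' exactly zero in both pure-source columns.
#'
#' With `noise = 0`, `compression = 1` and `background = 0` every array
#' feature's raw value is exactly linear in `f`, by construction.
#'
#' @param design a [TitrationDesign-class] whose replicate matrix covers
#'   the truth's platforms.
#' @param truth a [SyntheticTruth-class].
#' @param probes optional probe `GRanges` from [simulateProbes()]; when
#'   supplied, array features are probes (decoy probes report a 50/50 mix
#'   of their gene and their contaminant gene — the cross-hybridization
#'   the ambiguity filter exists to remove). Without probes, features are
#'   genes.
#' @param nControls number of negative-control features per array
#'   platform.
#' @param seed integer seed (defaults to the truth's seed).
#' @return named list of [PlatformMatrix-class], one per platform.
#' @export
simulateExpression <- function(design, truth, probes = NULL,
                               nControls = 50L, seed = truth@seed) {
  plat <- truth@platforms
  reps <- replicateCounts(design)
  if (!all(plat$platform %in% colnames(reps)))
    stop("design lacks replicate counts for some platforms")
  f <- bmoFraction(design)
  genes <- truth@genes
  # genes x samples expected abundance
  m <- outer(truth@baselineB, f) + outer(truth@baselineA, 1 - f)
  rownames(m) <- genes
  withr::with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(plat))) {
      p <- plat[i, ]
      if (p$noise < 0 || (!is.na(p$background) && p$background < 0) ||
          (!is.na(p$gain) && p$gain < 0))
        stop("negative platform parameters are not allowed")
      nr <- reps[, p$platform]
      sampleOf <- rep(sampleLabels(design), nr)
      repIdx <- unlist(lapply(nr, seq_len), use.names = FALSE)
      a <- m[, sampleOf, drop = FALSE]  # feature-level abundance
      featGene <- genes
      featIds <- genes
      if (!is.null(probes) && p$kind == "signal") {
        pp <- probes[mcols(probes)$platform == p$platform]
        if (length(pp)) {
          featIds <- mcols(pp)$probe_id
          featGene <- mcols(pp)$gene_id
          a <- m[featGene, sampleOf, drop = FALSE]
          contam <- mcols(pp)$contaminant
          hit <- !is.na(contam)
          if (any(hit))
            a[hit, ] <- (a[hit, , drop = FALSE] +
                         m[contam[hit], sampleOf, drop = FALSE]) / 2
        }
      }
      rownames(a) <- featIds
      if (p$kind == "signal") {
        noise <- exp(p$noise * matrix(rnorm(length(a)), nrow(a)))
        vals <- p$background + p$gain * a^p$compression * noise
        ctrl <- p$background *
          exp(p$noise * matrix(rnorm(nControls * ncol(a)), nControls))
        ctrlIds <- sprintf("%s:ctrl%03d", p$platform, seq_len(nControls))
        rownames(ctrl) <- ctrlIds
        vals <- rbind(vals, ctrl)
        # detection p-value: probability the signal is background-level
        pdet <- 1 - pnorm((log2(vals + 1) - log2(p$background + 1)) / 0.5)
        out[[p$platform]] <- PlatformMatrix(
          vals, kind = "signal", platform = p$platform,
          sample = sampleOf, replicate = repIdx, detectionP = pdet,
          isControl = c(rep(FALSE, length(featIds)),
                        rep(TRUE, nControls)))
      } else {
        ac <- a^p$compression
        ac[a == 0] <- 0
        share <- sweep(ac, 2, colSums(ac), "/")
        lib <- p$libSize * runif(ncol(a), 0.85, 1.15)
        mu <- sweep(share, 2, lib, "*")
        cnt <- if (p$noise > 0)
          matrix(rnbinom(length(mu), mu = mu, size = 1 / p$noise),
                 nrow(mu))
        else matrix(rpois(length(mu), mu), nrow(mu))
        dimnames(cnt) <- dimnames(mu)
        # noise genes: occasional low counts in mixture columns only
        ng <- which(truth@noiseGene[match(featGene, genes)])
        mixCol <- which(f[sampleOf] > 0 & f[sampleOf] < 1)
        if (length(ng) && length(mixCol)) {
          hit <- matrix(runif(length(ng) * length(mixCol)) < 0.35,
                        length(ng))
          low <- matrix(sample(1:12, length(ng) * length(mixCol),
                               replace = TRUE, prob = 0.65^(0:11)),
                        length(ng))
          block <- cnt[ng, mixCol, drop = FALSE]
          block[hit] <- low[hit]
          block[!hit] <- 0L
          cnt[ng, mixCol] <- block
        }
        out[[p$platform]] <- PlatformMatrix(
          cnt, kind = "count", platform = p$platform,
          sample = sampleOf, replicate = repIdx)
      }
    }
    out
  })
}

#' Simulate a complete synthetic titration study
#'
#' Convenience wrapper tying together truth, (optionally) annotation and
#' probes, and expression generation for the canonical five-sample
#' design over the default six-platform panel.
#'
#' @param nGenes number of genes.
#' @param platforms platform `data.frame`.
#' @param design a [TitrationDesign-class].
#' @param probeLevel if `TRUE`, also simulate annotation and probe
#'   intervals and emit array matrices at probe level.
#' @param decoyFraction decoy probe fraction (probe level only).
#' @param seed integer seed; fully determines the study.
#' @param ... passed to [simulateTruth()].
#' @return list with elements `design`, `truth`, `matrices` and, at probe
#'   level, `annotation` and `probes`.
#' @export
simulateStudy <- function(nGenes = 20000L, platforms = defaultPlatforms(),
                          design = canonicalTitrationDesign(platforms),
                          probeLevel = FALSE, decoyFraction = 0.05,
                          seed = 1L, ...) {
  truth <- simulateTruth(nGenes, platforms = platforms, seed = seed, ...)
  ann <- probes <- NULL
  if (probeLevel) {
    ann <- simulateAnnotation(nGenes, seed = seed)
    probes <- simulateProbes(ann, platforms,
                             decoyFraction = decoyFraction,
                             seed = seed + 1L)
  }
  mats <- simulateExpression(design, truth, probes = probes,
                             seed = seed + 2L)
  list(design = design, truth = truth, annotation = ann, probes = probes,
       matrices = mats)
}
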
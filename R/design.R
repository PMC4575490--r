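#' Source-B mixing fraction of a titration sample
#'
#' Parses a titration sample label and returns the proportion of source B
#' ("BMO", pure bone-marrow-like RNA) in the mixture. The canonical series
#' mixes pure source B into source A ("AGO") at ratios written `1:n`,
#' meaning one part source A per `n` total parts, so the source-B fraction
#' of `AG1BMn` is `(n - 1) / n`:
#' `AGO` -> 0, `AG1BM4` -> 0.75, `AG1BM16` -> 0.9375,
#' `AG1BM64` -> 0.984375, `BMO` -> 1.
#'
#' Note the ratio notation is *not* read as a:b parts A:B — under that
#' reading 1:4 would give 0.8, which contradicts the percentage series the
#' mixtures were prepared to (75 / 93.75 / 98.4375 %). The one-part-in-n
#' convention is the only reading consistent with those percentages.
#'
#' @param label character vector of sample labels. Either `"AGO"`, `"BMO"`,
#'   or `"AG<a>BM<n>"` with `a < n`, read as `a` parts source A per `n`
#'   total parts.
#' @return numeric vector of proportions in `[0, 1]`.
#' @examples
#' mixingFraction(c("AGO", "AG1BM4", "AG1BM16", "AG1BM64", "BMO"))
#' @export
mixingFraction <- function(label) {
  parse1 <- function(lab) {
    if (lab == "AGO") return(0)
    if (lab == "BMO") return(1)
    m <- regmatches(lab, regexec("^AG([0-9]+)BM([0-9]+)$", lab))[[1]]
    if (length(m) == 3) {
      a <- as.numeric(m[2]); n <- as.numeric(m[3])
      if (a < n) return((n - a) / n)
    }
    stop("cannot parse titration sample label: '", lab, "'", call. = FALSE)
  }
  vapply(as.character(label), parse1, numeric(1), USE.NAMES = TRUE)
}

#' Default synthetic platform panel
#'
#' Six platforms mirroring the structure of a four-microarray plus
#' two-RNA-seq comparison: `arrayA` is the wide-dynamic-range reference
#' array, `arrayB`/`arrayC` are compressed whole-transcript arrays,
#' `arrayD` is a noisy 3'-biased bead array, and `seqA`/`seqB` are
#' sequencing protocols. Per-platform parameters:
#'
#' * `kind` — `"signal"` (array-like) or `"count"` (sequencing-like);
#' * `compression` — power-law exponent `c` applied to abundance; the
#'   expected log2-ratio regression slope against an uncompressed platform,
#'   so `(1 - c) * 100` is the expected percent fold-change compression.
#'   Defaults span 0–69 % (about 50 % on average across the compressed
#'   platforms);
#' * `noise` — sdlog of multiplicative log-normal noise (arrays) or
#'   negative-binomial dispersion (sequencing);
#' * `background` — additive background signal (arrays only);
#' * `gain` — scale factor from abundance to signal;
#' * `libSize` — expected library size in reads (sequencing only);
#' * `probeLength`, `probesPerGene`, `placement` — probe geometry for the
#'   interval simulator (`"threeprime"` or `"whole"`).
#'
#' @return a `data.frame`, one row per platform.
#' @export
defaultPlatforms <- function() {
  data.frame(
    platform    = c("arrayA", "arrayB", "arrayC", "arrayD", "seqA", "seqB"),
    kind        = c("signal", "signal", "signal", "signal", "count", "count"),
    compression = c(1.0, 0.5, 0.45, 0.31, 0.73, 0.6),
    noise       = c(0.15, 0.2, 0.2, 0.5, 0.05, 0.1),
    background  = c(5, 20, 20, 30, 0, 0),
    # gain compensates the power-law so median signal is comparable
    # across platforms (2^(6 * (1 - c)) for log2-mean-6 baselines)
    gain        = c(1, 8, 9.85, 17.6, NA, NA),
    libSize     = c(NA, NA, NA, NA, 3e7, 3e7),
    probeLength   = c(60L, 25L, 25L, 50L, NA, NA),
    probesPerGene = c(1L, 6L, 8L, 2L, NA, NA),
    placement   = c("threeprime", "whole", "whole", "threeprime", NA, NA),
    stringsAsFactors = FALSE
  )
}

#' The canonical five-sample titration design
#'
#' Two pure source RNAs (`AGO`, `BMO`) and three mixtures in which pure
#' source B was titrated into source A at 1:4, 1:16 and 1:64 (one part A
#' per n total), giving source-B percentages 0, 75, 93.75, 98.4375 and
#' 100 %. Replicate counts per platform default to the structure of the
#' original six-platform study (1-3 technical replicates for arrays, one
#' library per sample for sequencing).
#'
#' @param platforms character vector of platform names, or a platform
#'   `data.frame` as from [defaultPlatforms()].
#' @param replicates optional samples x platforms integer matrix overriding
#'   the default replicate structure.
#' @return a [TitrationDesign-class].
#' @examples
#' canonicalTitrationDesign()
#' @export
canonicalTitrationDesign <- function(platforms = defaultPlatforms(),
                                     replicates = NULL) {
  if (is.data.frame(platforms)) platforms <- platforms$platform
  samples <- c("AGO", "AG1BM4", "AG1BM16", "AG1BM64", "BMO")
  if (is.null(replicates)) {
    defaults <- list(  # mirrors the study's replicate accounting
      arrayA = c(1L, 2L, 2L, 2L, 1L),
      arrayB = c(2L, 2L, 2L, 2L, 2L),
      arrayC = c(2L, 2L, 2L, 2L, 2L),
      arrayD = c(2L, 3L, 2L, 2L, 3L),
      seqA   = c(1L, 1L, 1L, 1L, 1L),
      seqB   = c(1L, 1L, 1L, 1L, 1L)
    )
    replicates <- vapply(platforms, function(p) {
      if (!is.null(defaults[[p]])) defaults[[p]] else rep(2L, 5L)
    }, integer(5))
    dimnames(replicates) <- list(samples, platforms)
  }
  TitrationDesign(samples, mixingFraction(samples), replicates)
}
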
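test_that("ambiguity filtering keeps exactly the uniquely-fully-aligned probes", {
  gr <- GRanges("chr1", IRanges(1:10 * 100, width = 25))
  mcols(gr)$probe_id <- paste0("p", 1:10)
  mcols(gr)$class <- c(rep("unique_full", 5), rep("multiple", 3),
                       rep("partial", 2))
  suppressMessages(kept <- filterAmbiguousProbes(gr))
  expect_identical(mcols(kept)$probe_id, paste0("p", 1:5))
  rem <- attr(kept, "removed")
  expect_identical(as.integer(rem[c("multiple", "partial")]), c(3L, 2L))
  allGood <- gr[1:5]
  expect_identical(length(suppressMessages(
    filterAmbiguousProbes(allGood))), 5L)
  expect_identical(length(suppressMessages(
    filterAmbiguousProbes(gr[0]))), 0L)
})

test_that("probe transcript sets require containment in the exon union", {
  ann <- fig1Annotation()
  probes <- fig1Probes()
  m <- assignTranscriptSets(probes, ann)
  # a probe in the region shared by t001 and t003-t005 reports that set
  r1 <- m[m$probe_id == "arrayA:p1", ]
  expect_identical(r1$transcript_set, "t001;t003;t004;t005")
  expect_identical(r1$gene_id, "TBP")
  # a probe inside the exon common to all transcripts reports the full set
  r3 <- m[m$probe_id == "arrayA:p2", ]
  expect_identical(r3$transcript_set, "t001;t002;t003;t004;t005")
  # a probe overlapping no exon is dropped
  lost <- GRanges("chr1", IRanges(9000, 9024))
  mcols(lost)$probe_id <- "lost"; mcols(lost)$platform <- "arrayA"
  expect_identical(nrow(assignTranscriptSets(lost, ann)), 0L)
  # a probe straddling an exon boundary is not contained
  edge <- GRanges("chr1", IRanges(1090, 1114))
  mcols(edge)$probe_id <- "edge"; mcols(edge)$platform <- "arrayA"
  expect_identical(nrow(assignTranscriptSets(edge, ann)), 0L)
  expect_error(assignTranscriptSets(
    GRanges("chrUn", IRanges(1, 25),
            probe_id = "x", platform = "arrayA"), ann), "chromosome")
})

test_that("multi-interval probes count a transcript only when all intervals are contained", {
  ann <- fig1Annotation()
  # two intervals: one in R1 (t001,t003-5), one in R3 (all five)
  gr <- GRanges("chr1", IRanges(c(1010, 3010), width = 25))
  mcols(gr)$probe_id <- c("j1", "j1")
  mcols(gr)$platform <- "arrayA"
  m <- assignTranscriptSets(gr, ann)
  expect_identical(m$transcript_set, "t001;t003;t004;t005")
})

test_that("pattern derivation recovers exactly the planted common patterns", {
  ann <- fig1Annotation()
  probes <- fig1Probes()
  platforms <- unique(mcols(probes)$platform)
  maps <- lapply(platforms, function(p)
    assignTranscriptSets(probes[mcols(probes)$platform == p], ann))
  names(maps) <- platforms
  pat <- deriveTranscriptPatterns(maps)
  expect_identical(patternKeys(pat),
                   sort(c("TBP\tt001;t003;t004;t005",
                          "TBP\tt001;t002;t003;t004;t005")))
  # both common patterns of the same gene stay separate data points
  expect_identical(length(pat), 2L)
  mem <- as.data.frame(patternMembers(pat))
  expect_identical(sort(unique(mem$platform)), sort(platforms))
  # the platform-private regions R2/R4/R5 never become patterns
  expect_false(any(patternKeys(pat) %in%
    c("TBP\tt002", "TBP\tt003", "TBP\tt001;t002")))
  # required platform missing -> error; disjoint sets -> zero patterns
  expect_error(deriveTranscriptPatterns(maps, c("arrayA", "arrayZ")),
               "arrayZ")
  disjoint <- list(
    a = data.frame(probe_id = "p1", platform = "a", gene_id = "g",
                   transcript_set = "t1"),
    b = data.frame(probe_id = "p2", platform = "b", gene_id = "g",
                   transcript_set = "t2"))
  expect_identical(length(deriveTranscriptPatterns(disjoint)), 0L)
})

test_that("pattern derivation agrees with the brute-force intersection oracle on random toy genes", {
  ann <- simulateAnnotation(50, seed = 61)
  probes <- simulateProbes(ann, decoyFraction = 0, seed = 62)
  platforms <- unique(mcols(probes)$platform)
  maps <- lapply(platforms, function(p)
    assignTranscriptSets(probes[mcols(probes)$platform == p], ann))
  names(maps) <- platforms
  # fast containment path vs explicit loop oracle, per platform
  for (p in platforms[1:2]) {
    bf <- bfAssignTranscriptSets(probes[mcols(probes)$platform == p], ann)
    got <- maps[[p]][order(maps[[p]]$probe_id), ]
    bf <- bf[order(bf$probe_id), ]
    expect_equal(got$transcript_set, bf$transcript_set,
                 ignore_attr = TRUE)
    expect_equal(got$gene_id, bf$gene_id, ignore_attr = TRUE)
  }
  pat <- deriveTranscriptPatterns(maps)
  expect_identical(patternKeys(pat),
                   gsub(";", ";", bfPatternKeys(maps)))
  # adding a required platform never increases the number of patterns
  p2 <- deriveTranscriptPatterns(maps, platforms[1:2])
  p3 <- deriveTranscriptPatterns(maps, platforms[1:3])
  expect_lte(length(p3), length(p2))
  # member features of different patterns never share a feature id
  mem <- as.data.frame(patternMembers(pat))
  expect_identical(anyDuplicated(paste(mem$platform, mem$feature_id)), 0L)
})

test_that("exons map to patterns by exact transcript-set equality", {
  ann <- fig1Annotation()
  probes <- fig1Probes()
  platforms <- unique(mcols(probes)$platform)
  maps <- lapply(platforms, function(p)
    assignTranscriptSets(probes[mcols(probes)$platform == p], ann))
  names(maps) <- platforms
  pat <- deriveTranscriptPatterns(maps)
  em <- mapExonsToPatterns(ann, pat)
  # R1's exon carries the t001/t003-5 set; R3 the full set; others unmapped
  expect_setequal(em$exon_id, c("TBP.R1", "TBP.R3"))
  # brute-force set comparison per exon on a random annotation
  ann2 <- simulateAnnotation(20, seed = 71)
  probes2 <- simulateProbes(ann2, decoyFraction = 0, seed = 72)
  maps2 <- lapply(platforms, function(p)
    assignTranscriptSets(probes2[mcols(probes2)$platform == p], ann2))
  names(maps2) <- platforms
  pat2 <- deriveTranscriptPatterns(maps2)
  em2 <- mapExonsToPatterns(ann2, pat2)
  pt <- patternTable(pat2)
  setOfPattern <- setNames(vapply(pt$transcripts, function(z)
    paste(sort(z), collapse = ";"), ""), pt$pattern_id)
  for (i in seq_len(nrow(em2))) {
    txs <- sort(unique(mcols(ann2)$transcript_id[
      mcols(ann2)$exon_id == em2$exon_id[i]]))
    expect_identical(paste(txs, collapse = ";"),
                     unname(setOfPattern[em2$pattern_id[i]]))
  }
})

test_that("gene alignment across platforms is the exact intersection", {
  l <- list(a = c("g1", "g2", "g3"), b = c("g2", "g3", "g4"),
            c = c("g3", "g2"))
  expect_identical(alignGenesAcrossPlatforms(l), c("g2", "g3"))
  expect_identical(alignGenesAcrossPlatforms(list(a = l$a, b = l$a)),
                   sort(l$a))
  expect_identical(alignGenesAcrossPlatforms(
    list(a = "g1", b = "g9")), character(0))
  # random toy lists vs pairwise fold
  set.seed(81)
  ls <- replicate(4, sample(paste0("g", 1:30), 20), simplify = FALSE)
  expect_identical(alignGenesAcrossPlatforms(ls),
                   sort(Reduce(intersect, ls)))
})
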
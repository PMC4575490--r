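test_that("absolute fold-change reciprocates downs and is an involution under reciprocal", {
  expect_equal(absoluteFoldChange(c(2, 0.25, 1)), c(2, 4, 1))
  expect_error(absoluteFoldChange(c(2, 0)), "> 0")
  set.seed(11)
  r <- rlnorm(200)
  expect_equal(absoluteFoldChange(r), absoluteFoldChange(1 / r))
  expect_true(all(absoluteFoldChange(r) >= 1))
})

test_that("fold-change tables hold the four contrasts against the pure source-A sample", {
  d <- canonicalTitrationDesign("p")
  v <- rbind(flat = rep(4, 5),
             up = c(2, 4, 6, 8, 10),
             down = c(8, 4, 2, 2, 1))
  pm <- PlatformMatrix(v, kind = "signal", platform = "p",
                       sample = sampleLabels(d))
  fct <- buildFoldChangeTable(pm, d)
  expect_identical(fct@contrasts,
                   c("AG1BM4", "AG1BM16", "AG1BM64", "BMO"))
  expect_equal(fct@contrastFraction, c(0.75, 0.9375, 0.984375, 1))
  expect_equal(unname(fct@ratio["flat", ]), rep(1, 4))
  expect_equal(unname(fct@ratio["up", ]), c(2, 3, 4, 5))
  expect_equal(unname(absFoldChange(fct)["down", ]), c(2, 4, 4, 8))
  expect_equal(log2Ratio(fct), log2(fct@ratio))
  # detected-only keeps detected genes; all-detected output is identical
  det <- c(flat = TRUE, up = TRUE, down = FALSE)
  sub <- buildFoldChangeTable(pm, d, detectedOnly = TRUE, detected = det)
  expect_identical(rownames(absFoldChange(sub)), c("flat", "up"))
  allDet <- buildFoldChangeTable(pm, d, detectedOnly = TRUE,
                                 detected = setNames(rep(TRUE, 3),
                                                     rownames(v)))
  expect_equal(absFoldChange(allDet), absFoldChange(fct))
  # log2-kind matrices are back-transformed before ratioing
  pmLog <- PlatformMatrix(log2(v + 1), kind = "signal", platform = "p",
                          sample = sampleLabels(d))
  pmLog@kind <- "log2"
  expect_equal(buildFoldChangeTable(pmLog, d)@ratio, fct@ratio)
  noAGO <- PlatformMatrix(v[, 2:5], kind = "signal", platform = "p",
                          sample = sampleLabels(d)[2:5])
  expect_error(buildFoldChangeTable(noAGO, d), "AGO")
})

test_that("average absolute fold-change is the mean of per-contrast means", {
  d <- canonicalTitrationDesign("p")
  set.seed(12)
  v <- matrix(rlnorm(25, 2), 5,
              dimnames = list(paste0("g", 1:5), NULL))
  pm <- PlatformMatrix(v, kind = "signal", platform = "p",
                       sample = sampleLabels(d))
  fct <- buildFoldChangeTable(pm, d)
  a <- absFoldChange(fct)
  avg <- averageAbsFC(fct)
  expect_equal(avg$perContrast, colMeans(a))
  expect_equal(avg$overall, mean(colMeans(a)))
  one <- averageAbsFC(fct, "g2")
  expect_equal(unname(one$perContrast), unname(a["g2", ]))
  # all-unity table gives overall 1
  flat <- PlatformMatrix(matrix(3, 4, 5), kind = "signal",
                         platform = "p", sample = sampleLabels(d))
  expect_equal(averageAbsFC(buildFoldChangeTable(flat, d))$overall, 1)
  expect_error(averageAbsFC(fct, character(0)), "empty")
  expect_error(averageAbsFC(fct, "nope"), "absent")
})

test_that("fold-change titration fidelity counts genes rising with the mixture fraction", {
  d <- canonicalTitrationDesign("p")
  v <- rbind(rising = c(2, 4, 6, 8, 10),    # abs FC strictly increasing
             constant = rep(5, 5),           # zero variance, excluded
             falling = c(10, 5, 4, 3, 2.5))  # abs FC decreasing? ratios<1
  pm <- PlatformMatrix(v, kind = "signal", platform = "p",
                       sample = sampleLabels(d))
  fct <- buildFoldChangeTable(pm, d)
  fid <- fcTitrationFidelity(fct, threshold = 0.5)
  r <- fid@correlations
  expect_gt(unname(r["rising"]), 0.5)
  expect_true(is.na(r["constant"]))
  expect_identical(fid@nEvaluable, 2L)
  # brute-force recomputation of the fraction
  a <- absFoldChange(fct)
  xs <- c(0.75, 0.9375, 0.984375, 1)
  rr <- apply(a, 1, function(z)
    if (sd(z) == 0) NA_real_ else cor(z, xs))
  expect_equal(fid@fraction, mean(rr[!is.na(rr)] > 0.5))
  # ordinal x-variable option
  fid2 <- fcTitrationFidelity(fct, xVar = "ordinal")
  rr2 <- apply(a, 1, function(z)
    if (sd(z) == 0) NA_real_ else cor(z, 1:4))
  expect_equal(fid2@fraction, mean(rr2[!is.na(rr2)] > 0.5))
})

test_that("fold-change enhancement is relative percent", {
  expect_equal(fcEnhancement(5, 5), 0)
  expect_equal(fcEnhancement(5, 6), 20)
  expect_equal(round(fcEnhancement(5.42, 8.88)), 64)
  expect_error(fcEnhancement(0, 1), "> 0")
})

test_that("fold-change compression recovers the regression slope", {
  set.seed(13)
  x <- rnorm(500, 0, 2)
  same <- fcCompression(x, x)
  expect_equal(same$slope, 1)
  expect_equal(same$compression, 0, tolerance = 1e-9)
  expect_equal(same$r.squared, 1)
  half <- fcCompression(x, 0.5 * x)
  expect_equal(half$compression, 50)
  # free intercept: shifts do not change the slope
  shifted <- fcCompression(x, 0.5 * x + 3)
  expect_equal(shifted$slope, 0.5)
  expect_error(fcCompression(x[1:2], x[1:2]), "3 finite")
  expect_error(fcCompression(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("restricting to clean features raises the average fold-change when cross-hybridizing decoys are present", {
  # decoy probes mix their gene with an unrelated gene, diluting the
  # fold-change; summaries over clean probes only must exceed summaries
  # over all probes (seed-averaged, 3-SE band)
  diffs <- vapply(1:6, function(seed) {
    ann <- simulateAnnotation(60, seed = seed)
    plat <- defaultPlatforms()[2, ]  # one compressed array platform
    design <- canonicalTitrationDesign(plat)
    probes <- simulateProbes(ann, plat, decoyFraction = 0.3,
                             seed = seed + 50)
    truth <- simulateTruth(unique(mcols(ann)$gene_id), plat,
                           pNoiseGene = 0, seed = seed)
    pm <- simulateExpression(design, truth, probes = probes,
                             seed = seed + 100)[[1]]
    gmap <- setNames(mcols(probes)$gene_id, mcols(probes)$probe_id)
    allSum <- collapseReplicates(summarizeToLevel(pm, gmap), design)
    clean <- probes[mcols(probes)$class == "unique_full"]
    cmap <- setNames(mcols(clean)$gene_id, mcols(clean)$probe_id)
    cleanSum <- collapseReplicates(summarizeToLevel(pm, cmap), design)
    common <- intersect(rownames(allSum), rownames(cleanSum))
    fcAll <- averageAbsFC(buildFoldChangeTable(allSum, design),
                          common)$overall
    fcClean <- averageAbsFC(buildFoldChangeTable(cleanSum, design),
                            common)$overall
    fcClean - fcAll
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs) + 3 * sd(diffs) / sqrt(length(diffs)), 0)
})
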
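test_that("quantile normalization matches the sorted-mean substitution oracle", {
  m <- matrix(c(5, 2, 9, 4, 1, 7), nrow = 3)
  got <- quantileNormalize(m)
  # hand computation: sorted columns (2,5,9) and (1,4,7); ref (1.5,4.5,8)
  expect_equal(unname(got),
               matrix(c(4.5, 1.5, 8, 4.5, 1.5, 8), nrow = 3))
  expect_equal(got, bfQuantileNorm(m))
  # defining property: column-wise sorted vectors pairwise equal
  set.seed(1)
  r <- matrix(rlnorm(600), 100)
  n1 <- quantileNormalize(r)
  srt <- apply(n1, 2, sort)
  expect_true(all(abs(srt - srt[, 1]) < 1e-12))
  # idempotence
  expect_equal(quantileNormalize(n1), n1, tolerance = 1e-9)
  # already-identical distributions are unchanged up to ordering
  perm <- cbind(sort(r[, 1]), sample(r[, 1]))
  expect_equal(sort(quantileNormalize(perm)[, 2]), sort(perm[, 2]))
  expect_error(quantileNormalize(r[, 1, drop = FALSE]), "2 columns")
  r[1, 1] <- NA
  expect_error(quantileNormalize(r), "missing")
})

test_that("quantile normalization agrees with limma on tie-free matrices and handles ties by span means", {
  skip_if_not_installed("limma")
  set.seed(2)
  for (i in 1:20) {
    m <- matrix(rlnorm(40 * 4), 40)
    expect_equal(unname(quantileNormalize(m)),
                 unname(limma::normalizeQuantiles(m, ties = TRUE)),
                 tolerance = 1e-12)
  }
  # a 3-long tie span gets the mean of all three reference values
  m <- cbind(c(1, 1, 1, 9), c(2, 4, 6, 8))
  ref <- rowMeans(cbind(c(1, 1, 1, 9), c(2, 4, 6, 8)))
  expect_equal(quantileNormalize(m)[1, 1], mean(ref[1:3]))
})

test_that("cpm normalization applies the add-then-scale rule", {
  m <- matrix(c(10, 0, 5, 3, 7, 2), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  got <- cpmNormalize(m, pseudocount = 1)
  expect_equal(got, bfCpm(m, 1))
  expect_equal(unname(colSums(got)), c(1e6, 1e6))
  expect_true(all(got > 0))
  # uniform counts give uniform cpm
  u <- matrix(4, 5, 2)
  expect_true(all(cpmNormalize(u, 0) == 1e6 / 5))
  # an all-zero feature still gets cpm = 1e6 / incremented library
  z <- rbind(m, g4 = c(0, 0))
  expect_equal(unname(cpmNormalize(z, 1)["g4", ]),
               unname(1e6 / (colSums(z) + 4)))
  expect_error(cpmNormalize(matrix(0, 2, 2), pseudocount = 0), "library")
  expect_error(cpmNormalize(matrix(numeric(0), 0, 0)), "empty")
  skip_if_not_installed("edgeR")
  set.seed(3)
  cnt <- matrix(rpois(200, 30), 50)
  expect_equal(unname(cpmNormalize(cnt, 1)),
               unname(edgeR::cpm(cnt + 1)), tolerance = 1e-9)
})

test_that("detection calls use strict thresholds and the any-member rule", {
  # feature detected iff any column strictly exceeds the cpm threshold
  v <- rbind(f1 = c(0.3, 0.1), f2 = c(0.25, 0.25), f3 = c(0.26, 0.1))
  pm <- PlatformMatrix(sweep(v, 2, colSums(v), "/") * 1e6, kind = "cpm",
                       platform = "p", sample = c("A", "B"))
  det <- detectionCalls(pm, rule = "cpm", cpmThreshold = 0.25)
  raw <- values(pm)
  expect_identical(unname(det),
                   unname(apply(raw > 0.25, 1, any)))
  # strictness at exactly the threshold
  pm2 <- PlatformMatrix(matrix(c(0.25, 0.25), 1), kind = "signal",
                        platform = "p", sample = c("A", "B"))
  pm2@kind <- "cpm"  # bypass column-sum validity for the 1-feature toy
  expect_false(unname(detectionCalls(pm2, rule = "cpm")))
  # gene detected iff any member feature detected in any sample
  sig <- PlatformMatrix(matrix(1, 5, 2), kind = "signal", platform = "p",
                        sample = c("A", "B"),
                        detectionP = cbind(c(0.2, 0.01, 0.5, 0.9, 0.8),
                                           c(0.6, 0.7, 0.8, 0.9, 0.6)))
  rownames(sig) <- paste0("f", 1:5)
  grp <- setNames(c("g1", "g1", "g1", "g2", "g2"), paste0("f", 1:5))
  res <- detectionCalls(sig, rule = "pvalue", pThreshold = 0.05,
                        grouping = grp)
  expect_identical(unname(res$group[c("g1", "g2")]), c(TRUE, FALSE))
  expect_error(detectionCalls(sig[, ], rule = "cpm"), "cpm")
  noP <- PlatformMatrix(matrix(1, 2, 2), kind = "signal", platform = "p",
                        sample = c("A", "B"))
  expect_error(detectionCalls(noP, rule = "pvalue"), "detection_p")
})

test_that("tukey biweight matches the direct weight-formula oracle and its invariants", {
  expect_identical(tukeyBiweight(c(7, 7, 7)), 7)
  expect_equal(tukeyBiweight(c(1, 2, 3)), 2)
  expect_equal(tukeyBiweight(c(1, 1, 1, 10)), bfBiweight(c(1, 1, 1, 10)))
  # the outlier is damped well below the plain mean
  expect_lt(tukeyBiweight(c(1, 1, 1, 10)), mean(c(1, 1, 1, 10)))
  expect_identical(tukeyBiweight(5), 5)
  expect_error(tukeyBiweight(numeric(0)), "finite")
  set.seed(4)
  for (i in 1:50) {
    x <- rnorm(sample(2:30, 1), sd = sample(c(0.1, 1, 10), 1))
    b <- tukeyBiweight(x)
    expect_equal(b, bfBiweight(x))
    expect_gte(b, min(x)); expect_lte(b, max(x))
    expect_equal(tukeyBiweight(sample(x)), b)
  }
})

test_that("summarization to pattern level biweights members on the log2 scale", {
  v <- rbind(f1 = c(8, 16), f2 = c(8, 16), f3 = c(8, 16), f4 = c(1000, 16))
  pm <- PlatformMatrix(v, kind = "signal", platform = "p",
                       sample = c("A", "B"))
  grp <- setNames(c("P1", "P1", "P1", "P1"), rownames(v))
  out <- summarizeToLevel(pm, grp)
  expect_identical(valueKind(out), "log2")
  expect_equal(values(out)["P1", ],
               c(A_r1 = bfBiweight(log2(c(8, 8, 8, 1000) + 1)),
                 B_r1 = log2(17)))
  # single-member group is just log2(value + 1)
  one <- summarizeToLevel(pm, c(f2 = "solo"))
  expect_equal(unname(values(one)["solo", ]), log2(c(8, 16) + 1))
  expect_error(summarizeToLevel(pm, c(nope = "P1")), "unknown")
})

test_that("replicate collapsing averages columns per sample", {
  v <- matrix(c(1, 2, 3, 5, 10, 20), nrow = 1,
              dimnames = list("g", NULL))
  pm <- PlatformMatrix(v, kind = "signal", platform = "p",
                       sample = c("A", "A", "B", "B", "C", "C"))
  out <- collapseReplicates(pm)
  expect_equal(unname(values(out)["g", ]), c(1.5, 4, 15))
  single <- PlatformMatrix(matrix(1:4, 2), kind = "signal",
                           platform = "p", sample = c("A", "B"))
  expect_equal(unname(values(collapseReplicates(single))),
               unname(matrix(1:4, 2)))
  d <- canonicalTitrationDesign()
  expect_error(collapseReplicates(single, d), "zero replicate")
})
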
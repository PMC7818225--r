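test_that("evidence difference maps sum subjects and are antisymmetric", {
  A <- matrix(c(1, 2, 3, 4), 2)
  B <- matrix(c(0, 0, 1, 1), 2)
  d <- deltaLME(A, B)
  expect_equal(d$groupSum, c(3, 5))
  expect_equal(d$perSubject, A - B)
  d2 <- deltaLME(B, A)
  expect_equal(d$perSubject + d2$perSubject, matrix(0, 2, 2))
  expect_equal(deltaLME(A, A)$groupSum, c(0, 0))
  expect_error(deltaLME(A, B[1, , drop = FALSE]), "same subjects")
})

test_that("group evidence differences reduce to RSS ratios at equal k", {
  set.seed(31)
  X <- list(exponential = buildDesign("exponential"),
            linear = buildDesign("linear"))
  Y <- matrix(rnorm(24 * 40), 24)
  fits <- lapply(X, fitGLM, Y = Y)
  lmes <- lapply(fits, computeLME)
  d <- deltaLME(matrix(lmes$exponential, 1), matrix(lmes$linear, 1))
  ref <- (24 / 2) * log(fits$linear@rss / fits$exponential@rss)
  expect_equal(d$groupSum, ref, tolerance = 1e-9)
})

test_that("conjunction masks intersect or unite", {
  m1 <- c(TRUE, TRUE, FALSE)
  m2 <- c(TRUE, FALSE, FALSE)
  expect_equal(conjunctionMask(list(m1, m1)), m1)
  expect_equal(conjunctionMask(list(m1, m1), "any"), m1)
  expect_equal(conjunctionMask(list(m1, m2)), c(TRUE, FALSE, FALSE))
  expect_equal(conjunctionMask(list(m1, m2), "any"), c(TRUE, TRUE, FALSE))
  expect_true(all(conjunctionMask(list(m1, m2)) <=
                    conjunctionMask(list(m1, m2), "any")))
})

test_that("signed-rank Z follows its closed-form null moments", {
  w <- wilcoxonSignedRank(1:10)
  expect_equal(w$W, 55)
  expect_equal(w$Z, (55 - 27.5) / sqrt(96.25), tolerance = 1e-12)
  expect_equal(w$Z, 2.8031, tolerance = 1e-4)
  # sign-symmetric sample
  x <- c(-3, -2, -1, 1, 2, 3)
  expect_equal(wilcoxonSignedRank(x)$Z, 0)
  set.seed(32)
  y <- rnorm(50)
  expect_equal(wilcoxonSignedRank(-y)$Z, -wilcoxonSignedRank(y)$Z)
  # agrees with the standard implementation (normal, no continuity corr.)
  ref <- wilcox.test(y, exact = FALSE, correct = FALSE)
  expect_equal(wilcoxonSignedRank(y)$p, ref$p.value, tolerance = 1e-10)
  expect_error(wilcoxonSignedRank(c(0, 0)), "zero")
})

test_that("one-sample KS statistic matches the reference implementation", {
  set.seed(33)
  x <- rnorm(200)
  ks <- ksStatistic(x)
  ref <- suppressWarnings(ks.test(x, "pnorm"))
  expect_equal(ks$D, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ks$D, ksStatistic(sample(x))$D)
  # shifted far from the reference: D approaches 1
  expect_gt(ksStatistic(x + 10)$D, 0.999)
  big <- rnorm(1e4)
  expect_lt(ksStatistic(big)$D, 0.05)
  expect_lt(ksStatistic(x + 1)$p, 1e-6)
})

test_that("comparison summaries reproduce independent re-aggregation", {
  set.seed(34)
  d <- deltaLME(matrix(rnorm(3 * 100, 1), 3), matrix(rnorm(3 * 100), 3),
                models = c("exponential", "linear"))
  row <- summarizeComparison(d)
  g <- colSums(d$perSubject)
  expect_equal(row$median, median(g))
  expect_equal(row$mean, mean(g))
  expect_equal(row$std, sd(g))
  expect_equal(row$pct_positive, 100 * mean(g > 0))
  expect_equal(row$wilcoxon_Z, wilcoxonSignedRank(g)$Z)
  # constant positive map
  dc <- deltaLME(matrix(2, 2, 10), matrix(1, 2, 10))
  rc <- summarizeComparison(dc)
  expect_equal(rc$median, 2)
  expect_equal(rc$std, 0)
  expect_equal(rc$pct_positive, 100)
  expect_error(summarizeComparison(d, rep(FALSE, 100)), "empty")
})

test_that("evidence histograms partition all selected voxels", {
  set.seed(35)
  d <- deltaLME(matrix(rnorm(2 * 500), 2), matrix(rnorm(2 * 500), 2))
  h <- deltaLMEHistogram(d)
  expect_equal(sum(h$count), 500)
  expect_true(all(h$bin_right > h$bin_left))
  sel <- rep(c(TRUE, FALSE), 250)
  expect_equal(sum(deltaLMEHistogram(d, sel)$count), 250)
})

test_that("evidence labels follow the conventional thresholds", {
  expect_equal(interpretEvidence(6), list(label = "very strong",
                                          favours = "A"))
  expect_equal(interpretEvidence(-6), list(label = "very strong",
                                           favours = "B"))
  expect_equal(interpretEvidence(0)$favours, "none")
  expect_equal(interpretEvidence(4)$label, "strong")
  expect_equal(interpretEvidence(2)$label, "positive")
  expect_error(interpretEvidence(NA))
})

test_that("exponential truth orders the models as expected in one dataset", {
  g <- testGrid()
  cfg <- scaledConfig(seed = 71)
  lmeL <- list(exponential = NULL, linear = NULL, chdet = NULL)
  for (s in 1:6) {
    av <- preprocess(simulateSubject(cfg, s, testMontage()))
    Y <- subjectVoxelMatrix(av, g)
    for (m in names(lmeL))
      lmeL[[m]] <- rbind(lmeL[[m]], computeLME(fitGLM(Y, buildDesign(m), s)))
  }
  info <- erpmass:::.maskInfo(scalpMask(g), 226)
  gtv <- groundTruthMask(cfg, g)[info$idx]
  dEL <- deltaLME(lmeL$exponential, lmeL$linear)$groupSum[gtv]
  dEC <- deltaLME(lmeL$exponential, lmeL$chdet)$groupSum[gtv]
  expect_gt(median(dEL), median(dEC))
  expect_gt(median(dEC), 0)
})
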
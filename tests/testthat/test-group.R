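test_that("block pooling averages the four modulator betas", {
  mk <- function(v) new("GLMFit",
                        betas = matrix(c(9, 9, 9, 9, v), ncol = 1),
                        rss = 1, n = 24L, k = 8L, model = "exponential",
                        tau = 1, subject = 1L, design = diag(2))
  expect_equal(poolBlocks(mk(c(1, 1, 1, 1))), 1)
  expect_equal(poolBlocks(mk(c(2, 0, 0, 0))), 0.5)
  expect_equal(poolBlocks(mk(c(1, 2, 3, 4))) + poolBlocks(mk(c(4, 3, 2, 1))),
               5)
})

test_that("the one-sample F equals the squared t statistic", {
  set.seed(21)
  x <- rnorm(17)
  spm <- oneSampleF(matrix(x, ncol = 1))
  tref <- mean(x) / (sd(x) / sqrt(17))
  expect_equal(spm@F, tref^2, tolerance = 1e-10)
  expect_equal(spm@F, unname(t.test(x)$statistic^2), tolerance = 1e-10)
  expect_equal(spm@df, c(1, 16))
  # antisymmetric sample has mean zero hence F = 0
  spm0 <- oneSampleF(matrix(c(-3, -1, 1, 3), ncol = 1))
  expect_equal(spm0@F, 0)
  expect_warning(spmInf <- oneSampleF(matrix(rep(2, 17), ncol = 1)),
                 "zero-variance")
  expect_true(is.infinite(spmInf@F))
  expect_error(oneSampleF(matrix(1, 1, 3)), "two subjects")
})

test_that("equivalent Z is exact at the F(1,16) median and invertible", {
  expect_equal(fToZ(qf(0.5, 1, 16), c(1, 16)), 0, tolerance = 1e-9)
  f <- seq(1, 100, length.out = 25)
  z <- fToZ(f, c(1, 16))
  p <- pnorm(z, lower.tail = FALSE)
  fBack <- qf(p, 1, 16, lower.tail = FALSE)
  expect_equal(fBack, f, tolerance = 1e-6)
  expect_true(all(diff(z) > 0))              # monotone in F
})

test_that("residual smoothness estimation recovers the applied kernel", {
  dims <- c(20L, 20L, 40L)
  idx <- seq_len(prod(dims))
  S <- 17
  set.seed(22)
  white <- matrix(rnorm(S * prod(dims)), S)
  fwW <- estimateSmoothness(sweep(white, 2, colMeans(white)), dims, idx)
  expect_equal(fwW, rep(sqrt(2 * log(2)), 3), tolerance = 0.2)
  mask3 <- array(TRUE, dims)
  smoothTo <- function(f) {
    sig <- rep(f, 3) / sqrt(8 * log(2))
    t(vapply(seq_len(S), function(s)
      as.vector(erpmass:::.smoothMasked(array(rnorm(prod(dims)), dims),
                                        mask3, sig)),
      numeric(prod(dims))))
  }
  m8 <- smoothTo(4)
  fw8 <- estimateSmoothness(sweep(m8, 2, colMeans(m8)), dims, idx)
  expect_equal(fw8, rep(4, 3), tolerance = 0.15)
  m2 <- smoothTo(2)
  fw2 <- estimateSmoothness(sweep(m2, 2, colMeans(m2)), dims, idx)
  expect_true(all(fwW < fw2 & fw2 < fw8))
})

test_that("the RFT threshold behaves monotonically and solves EC = alpha", {
  df <- c(1, 16)
  dims <- c(16L, 16L, 64L)
  idx <- seq_len(prod(dims))
  fw <- c(3.76, 3.76, 8)
  thr <- fweThreshold(df, fw, dims, idx, 0.05)
  resels <- reselCounts(dims, idx, fw)
  expect_equal(expectedEC(thr, df, resels), 0.05, tolerance = 1e-4)
  # doubling the search volume raises the threshold
  dims2 <- c(16L, 16L, 128L)
  thr2 <- fweThreshold(df, fw, dims2, seq_len(prod(dims2)), 0.05)
  expect_gt(thr2, thr)
  # doubling the smoothness lowers it
  thr3 <- fweThreshold(df, 2 * fw, dims, idx, 0.05)
  expect_lt(thr3, thr)
  expect_error(fweThreshold(df, fw, dims, idx, alpha = 1.5), "alpha")
  expect_error(expectedEC(10, c(4, 16), resels), "df1")
})

test_that("cluster extraction labels blobs and reports ordered peaks", {
  g <- testGrid()
  dims <- c(g@n, g@n, 20L)
  info <- erpmass:::.maskInfo(scalpMask(g), 20L)
  Fv <- rep(1, length(info$idx))
  mkSpm <- function(Fv) new("SPMMap", F = Fv, Z = fToZ(Fv, c(1, 16)),
                            df = c(1, 16), mean = Fv, nSubjects = 17L,
                            maskDim = dims, maskIdx = info$idx,
                            times = seq(50, by = 2, length.out = 20))
  expect_equal(nrow(extractClusters(mkSpm(Fv), 10, g)), 0)
  # one suprathreshold voxel
  F1 <- Fv
  F1[500] <- 50
  tab1 <- extractClusters(mkSpm(F1), 10, g)
  expect_equal(nrow(tab1), 1)
  expect_equal(tab1$size, 1)
  expect_equal(tab1$F, 50)
  # two well-separated blobs, sizes 2 and 1, sorted descending
  F2 <- Fv
  vol <- array(NA_real_, dims)
  vol[info$idx] <- F2
  centre <- c(16, 16, 3)
  vol[16, 16, 3] <- 40; vol[16, 17, 3] <- 35    # blob A (size 2)
  vol[16, 16, 15] <- 60                          # blob B (size 1)
  tab2 <- extractClusters(mkSpm(vol[info$idx]), 10, g)
  expect_equal(length(unique(tab2$activation)), 2)
  sizes <- tapply(tab2$size, tab2$activation, unique)
  expect_equal(as.vector(sizes), c(2, 1))        # ordered by size
  expect_true(all(tab2$latency_ms >= 50 & tab2$latency_ms <= 500))
})
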
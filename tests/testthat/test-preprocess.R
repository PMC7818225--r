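mkSignal <- function(v, montage = testMontage(), fs = 500) {
  nch <- length(channelLabels(montage)) + length(eogChannels(montage))
  arr <- array(rep(v, each = nch), c(1, nch, length(v)))
  epochsFromArray(arr, montage, seq(0, by = 1000 / fs,
                                    length.out = length(v)), fs)
}

test_that("zero-phase band-pass removes DC and passes the band", {
  times <- seq(0, 2000, by = 2)
  dc <- bandpassFilter(mkSignal(rep(7, length(times))))
  expect_lt(max(abs(epochData(dc))), 0.07)          # < 1% of input
  s10 <- bandpassFilter(mkSignal(sin(2 * pi * 10 * times / 1000)))
  mid <- 300:700
  expect_equal(max(abs(epochData(s10)[1, 1, mid])), 1, tolerance = 0.05)
})

test_that("stop-band attenuation matches the analytic Butterworth response", {
  fs <- 500
  times <- seq(0, 2000, by = 1000 / fs)
  s60 <- bandpassFilter(mkSignal(sin(2 * pi * 60 * times / 1000)))
  measured <- max(abs(epochData(s60)[1, 1, 300:700]))
  # independent oracle: evaluate the designed digital filters at 60 Hz
  polyval <- function(co, z) {
    out <- 0 + 0i
    for (c0 in co) out <- out * z + c0
    out
  }
  z <- exp(-1i * 2 * pi * 60 / fs)
  lp <- signal::butter(4, 2 * 30 / fs, "low")
  hp <- signal::butter(4, 2 * 1 / fs, "high")
  H <- Mod(polyval(lp$b, z) / polyval(lp$a, z)) *
    Mod(polyval(hp$b, z) / polyval(hp$a, z))
  expect_equal(measured, H^2, tolerance = 0.05)     # zero phase: |H|^2
  expect_error(bandpassFilter(mkSignal(sin(times)),
                              preprocConfig(bandHz = c(1, 300))),
               "Nyquist")
})

test_that("common-average re-reference zeroes the scalp mean and is idempotent", {
  m <- miniMontage(2)
  arr <- array(c(3, -1), c(1, 2, 1))
  ep <- epochsFromArray(arr, m, 0)
  out <- rereferenceCommonAverage(ep)
  expect_equal(as.vector(epochData(out)), c(2, -2))
  set.seed(1)
  ep2 <- epochsFromArray(array(rnorm(5 * 65 * 20), c(5, 65, 20)),
                         testMontage(), seq(0, by = 2, length.out = 20))
  r1 <- rereferenceCommonAverage(ep2)
  expect_lt(max(abs(apply(epochData(r1)[, 1:61, ], c(1, 3), mean))), 1e-9)
  r2 <- rereferenceCommonAverage(r1)
  expect_equal(epochData(r2), epochData(r1), tolerance = 1e-12)
  # EOG channels are untouched
  expect_identical(epochData(r1)[, 62:65, ], epochData(ep2)[, 62:65, ])
})

test_that("baseline correction zero-means the pre-stimulus window", {
  m <- miniMontage(3)
  times <- seq(-100, 100, by = 2)
  arr <- array(7, c(2, 3, length(times)))
  ep <- epochsFromArray(arr, m, times)
  out <- baselineCorrect(ep, c(-100, 0))
  expect_true(all(abs(epochData(out)) < 1e-12))
  set.seed(2)
  ep2 <- epochsFromArray(array(rnorm(2 * 3 * length(times)),
                               c(2, 3, length(times))), m, times)
  b1 <- baselineCorrect(ep2, c(-100, 0))
  idx <- which(times >= -100 & times <= 0)
  expect_lt(max(abs(apply(epochData(b1)[, , idx], c(1, 2), mean))), 1e-9)
  expect_equal(epochData(baselineCorrect(b1, c(-100, 0))),
               epochData(b1), tolerance = 1e-12)
  expect_error(baselineCorrect(ep2, c(-900, -800)), "no samples")
})

test_that("threshold rejection removes exactly the above-threshold trials", {
  m <- testMontage()
  times <- seq(-100, 550, by = 2)
  nch <- 65
  arr <- array(0, c(3, nch, length(times)))
  arr[2, 63, 100] <- 80                      # EOG channel excursion
  ep <- epochsFromArray(arr, m, times)
  out <- rejectArtifacts(ep, 75)
  expect_identical(out$rejected, 2L)
  expect_equal(nTrials(out$retained), 2)
  expect_identical(trialInfo(out$retained)$object, c(1L, 3L))
  clean <- rejectArtifacts(epochsFromArray(array(1, c(4, nch, 10)), m,
                                           seq_len(10) * 2), 75)
  expect_length(clean$rejected, 0)
})

test_that("injected artifacts are exactly the trials later rejected", {
  cfg <- scaledConfig(seed = 13, nObjectsPerBlock = 10)   # 240 trials
  ep <- simulateSubject(cfg, 1, testMontage())
  out <- injectArtifacts(ep, fraction = 0.1, magnitudeUv = 120, seed = 4)
  rej <- rejectArtifacts(out$epochs, 75)
  expect_identical(rej$rejected, out$indices)
  expect_length(rej$rejected, 24)
})

test_that("trials shortly after a distractor target are excluded", {
  m <- miniMontage(3)
  arr <- array(0, c(3, 3, 5))
  tr <- data.frame(subject = 1L, block = 1L, object = 1:3,
                   presentation = 1L, onset = c(1000, 1500, 1900))
  ep <- epochsFromArray(arr, m, seq_len(5) * 2, trials = tr)
  expect_identical(excludeNearTarget(ep, numeric()), ep)
  out <- excludeNearTarget(ep, 1000, 800)    # 1500 dropped, 1900 kept
  expect_identical(trialInfo(out)$onset, c(1000, 1900))
})

test_that("condition averaging produces correct cell means and counts", {
  m <- miniMontage(2)
  arr <- array(0, c(4, 2, 3))
  arr[1, , ] <- 0; arr[2, , ] <- 2           # two trials of one cell
  tr <- data.frame(subject = 1L, block = 1L,
                   object = c(1L, 2L, 1L, 2L),
                   presentation = c(1L, 1L, 2L, 2L),
                   onset = 0:3 * 570)
  ep <- epochsFromArray(arr, m, 1:3 * 2, trials = tr)
  av <- averageByCondition(ep)
  expect_equal(av@means[1, 1, , ], matrix(1, 2, 3))
  expect_equal(sum(trialCounts(av)), 4)
  ep2 <- epochsFromArray(arr[-c(3, 4), , , drop = FALSE], m, 1:3 * 2,
                         trials = tr[-c(3, 4), ])
  expect_error(averageByCondition(ep2, nPresentations = 2),
               "block 1, presentation 2")
})

test_that("rejection never changes the mean of untouched cells", {
  cfg <- scaledConfig(seed = 17, nObjectsPerBlock = 3)
  ep <- simulateSubject(cfg, 1, testMontage())
  out <- injectArtifacts(ep, fraction = 0.05, magnitudeUv = 200, seed = 5)
  rej <- rejectArtifacts(out$epochs, 75)
  avAll <- averageByCondition(ep)
  avRej <- averageByCondition(rej$retained)
  tr <- trialInfo(ep)
  touched <- unique(tr[out$indices, c("block", "presentation")])
  for (b in 1:4) for (r in 1:6) {
    if (any(touched$block == b & touched$presentation == r)) next
    expect_equal(avRej@means[b, r, , ], avAll@means[b, r, , ],
                 tolerance = 1e-12)
  }
})

test_that("the preprocess entry point applies the documented stage order", {
  cfg <- scaledConfig(seed = 19, nObjectsPerBlock = 2)
  ep <- simulateSubject(cfg, 1, testMontage())
  av <- preprocess(ep)
  manual <- averageByCondition(rejectArtifacts(
    baselineCorrect(rereferenceCommonAverage(bandpassFilter(ep)),
                    c(-100, 0)), 75)$retained)
  expect_equal(av@means, manual@means, tolerance = 1e-12)
  expect_equal(dim(av@means)[1:2], c(4L, 6L))
  expect_match(av@metadata$rejectionRule$appliedTo, "baseline")
})
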
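test_that("repetition dynamics follow the three generative conventions", {
  expect_equal(repetitionDynamics("exponential", 6, tau = 1),
               exp(-(0:5)))
  expect_equal(repetitionDynamics("categorical", 6), c(1, 0, 0, 0, 0, 0))
  expect_equal(repetitionDynamics("linear", 6), seq(1, 0, length.out = 6))
  expect_error(repetitionDynamics("cubic", 6))
})

test_that("effect specification validates its fields", {
  expect_error(effectSpec("Oz", c(100, 600), 2), "within")
  expect_error(effectSpec("Oz", c(100, 140), Inf), "finite")
  expect_error(effectSpec("Oz", c(100, 140), 2, tau = 0), "tau")
  expect_error(effectSpec("Oz", c(100, 140), 2, sign = 2), "sign")
  expect_error(simulateSubject(simulationConfig(
    effects = list(effectSpec("XX9", c(100, 140), 2)), noiseSd = 0,
    nObjectsPerBlock = 1), 1), "XX9")
})

test_that("simulation is bit-reproducible and respects the design counts", {
  cfg <- scaledConfig(seed = 5, nObjectsPerBlock = 2)
  e1 <- simulateSubject(cfg, 2, testMontage())
  e2 <- simulateSubject(cfg, 2, testMontage())
  expect_identical(epochData(e1), epochData(e2))
  expect_identical(trialInfo(e1), trialInfo(e2))
  tr <- trialInfo(e1)
  expect_equal(nrow(tr), 4 * 2 * 6)
  expect_true(all(tr$presentation %in% 1:6))
  expect_equal(length(sampleTimes(e1)), 326)   # -100..550 ms at 500 Hz
  # different subjects draw different data
  expect_false(identical(epochData(e1),
                         epochData(simulateSubject(cfg, 3, testMontage()))))
  expect_error(simulateSubject(cfg, 99), "nSubjects")
})

test_that("noise-free trials are identical across presentations without effects", {
  cfg <- simulationConfig(nObjectsPerBlock = 2, noiseSd = 0,
                          effects = list(), subjectSd = 0)
  ep <- simulateSubject(cfg, 1, testMontage())
  d <- epochData(ep)
  tr <- trialInfo(ep)
  i1 <- which(tr$block == 1 & tr$object == 1)
  for (i in i1[-1]) expect_equal(d[i, , ], d[i1[1], , ])
})

test_that("exponential effect decays by e^-1 per presentation at tau = 1", {
  eff <- effectSpec("Oz", c(100, 140), amplitude = 2, sign = 1,
                    dynamics = "exponential", tau = 1)
  base <- simulationConfig(nObjectsPerBlock = 1, noiseSd = 0,
                           subjectSd = 0, effects = list())
  cfg <- simulationConfig(nObjectsPerBlock = 1, noiseSd = 0,
                          subjectSd = 0, effects = list(eff))
  m <- testMontage()
  d0 <- epochData(simulateSubject(base, 1, m))
  d1 <- epochData(simulateSubject(cfg, 1, m))
  oz <- which(channelLabels(m) == "Oz")
  ti <- which.min(abs(sampleTimes(simulateSubject(cfg, 1, m)) - 120))
  tr <- trialInfo(simulateSubject(cfg, 1, m))
  sig <- d1[, oz, ti] - d0[, oz, ti]
  p1 <- sig[tr$block == 1 & tr$presentation == 1]
  p2 <- sig[tr$block == 1 & tr$presentation == 2]
  expect_equal(p2 / p1, exp(-1), tolerance = 1e-9)
  expect_equal(p1, 2, tolerance = 1e-9)
  # linearity: doubling amplitude doubles the effect signal everywhere
  eff2 <- effectSpec("Oz", c(100, 140), amplitude = 4, sign = 1, tau = 1)
  cfg2 <- simulationConfig(nObjectsPerBlock = 1, noiseSd = 0,
                           subjectSd = 0, effects = list(eff2))
  d2 <- epochData(simulateSubject(cfg2, 1, m))
  expect_equal(d2 - d0, 2 * (d1 - d0), tolerance = 1e-9)
})

test_that("artifact injection corrupts exactly the requested trials", {
  cfg <- scaledConfig(seed = 9, nObjectsPerBlock = 10)   # 240 trials
  ep <- simulateSubject(cfg, 1, testMontage())
  out0 <- injectArtifacts(ep, fraction = 0, magnitudeUv = 100)
  expect_identical(epochData(out0$epochs), epochData(ep))
  expect_length(out0$indices, 0)
  out <- injectArtifacts(ep, fraction = 0.1, magnitudeUv = 100, seed = 3)
  expect_length(out$indices, 24)
  d <- epochData(out$epochs)
  for (i in out$indices)
    expect_gt(max(abs(d[i, , ])), 100)
  expect_error(injectArtifacts(ep, 0.1, magnitudeUv = 60), "75")
})

test_that("noise correlation between channels decays with distance", {
  cfg <- simulationConfig(nObjectsPerBlock = 4, effects = list(),
                          noiseSd = 10, seed = 31)
  m <- testMontage()
  ep <- simulateSubject(cfg, 1, m)
  d <- epochData(ep)[, 1:61, ]
  X <- matrix(aperm(d, c(3, 1, 2)), ncol = 61)
  C <- cor(X)
  P <- channelPositions(m)
  arc <- 85 * acos(pmin(pmax(tcrossprod(P), -1), 1))
  up <- upper.tri(C)
  bins <- cut(arc[up], breaks = c(0, 40, 80, 120, 300))
  mc <- tapply(C[up], bins, mean)
  expect_true(all(diff(mc) < 0))
})

test_that("ground-truth mask marks effect footprints inside the scalp", {
  g <- testGrid()
  cfg0 <- simulationConfig(effects = list())
  expect_false(any(groundTruthMask(cfg0, g)))
  eff <- effectSpec("Oz", c(86, 140), 2)
  cfg <- simulationConfig(effects = list(eff))
  gt <- groundTruthMask(cfg, g)
  times <- seq(50, 500, by = 2)
  frames <- apply(gt, 3, any)
  expect_identical(which(frames), which(times >= 86 & times <= 140))
  maskRep <- array(scalpMask(g), dim(gt))
  expect_true(all(maskRep[gt]))
})
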
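# shared fixtures, built once per test run

testMontage <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- makeDefaultMontage()
    m
  }
})

testGrid <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- scalpGrid(testMontage())
    g
  }
})

# scaled-down study configuration: 2 objects per block with the single-trial
# noise rescaled so the condition-mean noise equals the full design's
# 12/sqrt(60) microvolts
scaledConfig <- function(seed = 1L, nObjectsPerBlock = 2L, ...) {
  simulationConfig(nObjectsPerBlock = nObjectsPerBlock,
                   noiseSd = 12 * sqrt(nObjectsPerBlock / 60),
                   seed = seed, ...)
}

# minimal montage with a handful of channels on the unit sphere
miniMontage <- function(n = 4) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  P <- cbind(sin(pi / 4) * cos(ang), sin(pi / 4) * sin(ang),
             rep(cos(pi / 4), n))
  labs <- paste0("ch", seq_len(n))
  dimnames(P) <- list(labs, c("x", "y", "z"))
  new("Montage", labels = labs, positions = P, eogLabels = character())
}

# EpochSet from an explicit trials x channels x samples array
epochsFromArray <- function(data, montage, times, fs = 500,
                            trials = NULL) {
  n <- dim(data)[1]
  if (is.null(trials))
    trials <- data.frame(subject = 1L, block = 1L, object = seq_len(n),
                         presentation = 1L, onset = (seq_len(n) - 1) * 570)
  new("EpochSet", data = data, trials = trials, times = times,
      samplingRate = fs, montage = montage, metadata = list())
}

# single-subject noise-free averages for GLM recovery checks: skips
# filtering and re-referencing so the generative amplitude is preserved
noiseFreeAverages <- function(cfg, subjectId = 1) {
  averageByCondition(simulateSubject(cfg, subjectId, testMontage()))
}
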
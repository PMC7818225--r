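# Multi-subject synthetic ERP generator with known ground-truth repetition
# dynamics. The generator emulates the repetition design it is meant to
# exercise: 17 subjects, 4 blocks of 60 objects presented 6 times each at a
# 570 ms SOA, 61 scalp + 4 EOG channels at 500 Hz, epochs -100..550 ms,
# canonical posterior P1/P2 deflections, and additive repetition effects
# whose amplitude follows g(r) across presentations.

#' Repetition dynamics g(r)
#'
#' Ground-truth and regressor convention shared across the package:
#' exponential g(r) = exp(-(r-1)/tau); categorical g(r) = 1 for the first
#' presentation and 0 after; linear g(r) decreasing from 1 to 0 in equal
#' steps.
#'
#' @param dynamics one of "exponential", "categorical", "linear".
#' @param nPresentations number of presentations.
#' @param tau exponential decay constant, in presentation units.
#' @return numeric vector g(1..nPresentations).
#' @export
repetitionDynamics <- function(dynamics, nPresentations = 6L, tau = 1) {
  r <- seq_len(nPresentations)
  switch(match.arg(dynamics, c("exponential", "categorical", "linear")),
         exponential = exp(-(r - 1) / tau),
         categorical = as.numeric(r == 1L),
         linear = 1 - (r - 1) / (nPresentations - 1))
}

#' Specify a ground-truth repetition effect
#'
#' An effect is a spatially weighted (planar Gaussian around a centre
#' channel), temporally windowed deflection whose amplitude across
#' presentations follows \code{sign * amplitude * g(r)}. With a decaying
#' g, \code{sign = +1} yields a deflection that is largest on the first
#' presentation and shrinks over repetitions (repetition suppression of a
#' positive component; positive modulator beta), \code{sign = -1} a
#' measured value that rises towards zero over repetitions (repetition
#' enhancement; negative beta).
#'
#' @param centerChannel channel name at the spatial peak.
#' @param windowMs numeric [start, end] in ms post-stimulus, inside the
#'   epoch window.
#' @param amplitude effect magnitude in microvolts at presentation 1.
#' @param sign +1 or -1, see above.
#' @param spatialFwhmMm full-width at half-maximum of the spatial weight on
#'   the projected scalp, in mm.
#' @param dynamics,tau see \code{\link{repetitionDynamics}}.
#' @param rampMs raised-cosine on/off ramp at the window edges.
#' @return an object of class "EffectSpec".
#' @export
effectSpec <- function(centerChannel, windowMs, amplitude, sign = 1,
                       spatialFwhmMm = 40, dynamics = "exponential",
                       tau = 1, rampMs = 10) {
  stopifnot(length(windowMs) == 2L, windowMs[1] < windowMs[2])
  if (windowMs[1] < -100 || windowMs[2] > 550)
    stop("effect window must lie within [-100, 550] ms")
  if (!is.finite(amplitude)) stop("amplitude must be finite")
  if (tau <= 0) stop("tau must be positive")
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  dynamics <- match.arg(dynamics, c("exponential", "categorical", "linear"))
  structure(list(centerChannel = centerChannel, windowMs = windowMs,
                 amplitude = amplitude, sign = sign,
                 spatialFwhmMm = spatialFwhmMm, dynamics = dynamics,
                 tau = tau, rampMs = rampMs),
            class = "EffectSpec")
}

#' Default ground-truth effects
#'
#' Four space-time regions emulating the canonical repetition findings the
#' generator is calibrated to: early occipital suppression (86-140 ms),
#' occipitotemporal enhancement (320-340 ms), right temporoparietal
#' suppression (322-360 ms) and right frontotemporal suppression
#' (400-446 ms), all with exponential dynamics (tau = 1).
#'
#' @return list of \code{\link{effectSpec}} objects.
#' @export
defaultEffects <- function() {
  list(
    effectSpec("Oz",  c(86, 140),  amplitude = 7.0, sign = +1),
    effectSpec("POz", c(320, 340), amplitude = 6.5, sign = -1),
    effectSpec("TP8", c(322, 360), amplitude = 7.0, sign = +1),
    effectSpec("FT8", c(400, 446), amplitude = 8.0, sign = +1))
}

#' Simulation configuration
#'
#' Defaults are the study conditions the package emulates: 17 subjects,
#' 4 blocks x 60 objects x 6 presentations, 61+4 channels at 500 Hz,
#' epochs -100..550 ms, 570 ms SOA. Noise is spatially correlated
#' (correlation exp(-distance/lambda) over scalp-arc distance) Gaussian
#' noise shaped to the 1-30 Hz band; between-subject variability draws each
#' effect amplitude once per subject from Normal(amplitude, subjectSd^2)
#' truncated at zero.
#'
#' @param nSubjects,nBlocks,nObjectsPerBlock,nPresentations design counts.
#' @param samplingRate Hz.
#' @param epochWindowMs epoch limits in ms relative to stimulus onset.
#' @param effects list of \code{\link{effectSpec}}.
#' @param noiseSd single-trial noise standard deviation per channel and
#'   sample, microvolts.
#' @param noiseSpatialCorrMm spatial correlation length lambda, mm of
#'   scalp arc.
#' @param noiseBandHz band the noise is shaped to.
#' @param subjectSd between-subject SD of effect amplitudes, microvolts.
#' @param soaMs stimulus onset asynchrony in ms.
#' @param seed integer seed recorded in the output metadata.
#' @return an object of class "SimulationConfig".
#' @export
simulationConfig <- function(nSubjects = 17L, nBlocks = 4L,
                             nObjectsPerBlock = 60L, nPresentations = 6L,
                             samplingRate = 500, epochWindowMs = c(-100, 550),
                             effects = defaultEffects(), noiseSd = 12,
                             noiseSpatialCorrMm = 50, noiseBandHz = c(1, 30),
                             subjectSd = 2.8, soaMs = 570, seed = 1L) {
  counts <- c(nSubjects, nBlocks, nObjectsPerBlock, nPresentations)
  if (any(counts < 1)) stop("all design counts must be >= 1")
  if (samplingRate <= 0) stop("sampling rate must be positive")
  structure(list(nSubjects = as.integer(nSubjects),
                 nBlocks = as.integer(nBlocks),
                 nObjectsPerBlock = as.integer(nObjectsPerBlock),
                 nPresentations = as.integer(nPresentations),
                 samplingRate = samplingRate, epochWindowMs = epochWindowMs,
                 effects = effects, noiseSd = noiseSd,
                 noiseSpatialCorrMm = noiseSpatialCorrMm,
                 noiseBandHz = noiseBandHz, subjectSd = subjectSd,
                 soaMs = soaMs, seed = as.integer(seed)),
            class = "SimulationConfig")
}

# planar Gaussian spatial weights over scalp channels around a centre
.spatialWeights <- function(montage, centerChannel, fwhmMm, rimMm = 60) {
  co <- projectElectrodes(montage, rimMm = rimMm)
  if (!centerChannel %in% rownames(co))
    stop(sprintf("unknown centre channel '%s'", centerChannel))
  sigma <- fwhmMm / sqrt(8 * log(2))
  d2 <- (co[, 1] - co[centerChannel, 1])^2 +
    (co[, 2] - co[centerChannel, 2])^2
  exp(-d2 / (2 * sigma^2))
}

# raised-cosine windowed indicator of [w1, w2] over the time axis
.timeWindow <- function(times, windowMs, rampMs) {
  w <- numeric(length(times))
  inside <- times >= windowMs[1] & times <= windowMs[2]
  w[inside] <- 1
  if (rampMs > 0) {
    up <- times >= windowMs[1] - rampMs & times < windowMs[1]
    dn <- times > windowMs[2] & times <= windowMs[2] + rampMs
    w[up] <- 0.5 * (1 + cos(pi * (windowMs[1] - times[up]) / rampMs))
    w[dn] <- 0.5 * (1 + cos(pi * (times[dn] - windowMs[2]) / rampMs))
  }
  w
}

# canonical posterior base waveform: P1 (~100 ms) and P2 (~220 ms)
.baseWaveform <- function(times, montage) {
  wOz <- .spatialWeights(montage, "Oz", 70)
  wPOz <- .spatialWeights(montage, "POz", 80)
  p1 <- 5 * exp(-(times - 100)^2 / (2 * 12^2))
  p2 <- 4 * exp(-(times - 220)^2 / (2 * 25^2))
  outer(p1, wOz) + outer(p2, wPOz)        # samples x channels
}

# scalp + EOG noise covariance factor: exp(-arc/lambda) across scalp
# channels, independent EOG; returns the upper Cholesky factor
.noiseChol <- function(montage, lambdaMm, headRadiusMm = 85) {
  P <- montage@positions
  G <- tcrossprod(P)
  arc <- headRadiusMm * acos(pmin(pmax(G, -1), 1))
  C <- exp(-arc / lambdaMm)
  diag(C) <- diag(C) + 1e-8
  U <- chol(C)
  nE <- length(montage@eogLabels)
  nS <- nrow(P)
  out <- diag(nS + nE)
  out[seq_len(nS), seq_len(nS)] <- U
  out
}

#' Simulate one subject's epoched ERP data
#'
#' Every trial is base waveform + sum of ground-truth repetition effects at
#' the trial's presentation index + spatially and temporally correlated
#' noise; the output is bit-reproducible given (config seed, subjectId).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param subjectId integer in 1..nSubjects.
#' @param montage a \linkS4class{Montage}; the default 61-channel layout if
#'   missing.
#' @return An \linkS4class{EpochSet} with trials in block-major order
#'   (block, object, presentation).
#' @export
simulateSubject <- function(config, subjectId,
                            montage = makeDefaultMontage()) {
  stopifnot(is(montage, "Montage"))
  if (subjectId < 1 || subjectId > config$nSubjects)
    stop("subjectId must lie in 1..nSubjects")
  fs <- config$samplingRate
  times <- seq(config$epochWindowMs[1], config$epochWindowMs[2],
               by = 1000 / fs)
  ns <- length(times)
  nScalp <- length(montage@labels)
  nch <- nScalp + length(montage@eogLabels)
  nb <- config$nBlocks; no <- config$nObjectsPerBlock
  np <- config$nPresentations
  ntr <- nb * no * np

  set.seed(.subseed(config$seed, subjectId))
  # per-subject effect amplitudes ~ Normal(A, subjectSd^2) truncated at 0
  amps <- vapply(config$effects, function(e) {
    a <- rnorm(1, e$amplitude, config$subjectSd)
    while (a < 0) a <- rnorm(1, e$amplitude, config$subjectSd)
    a
  }, numeric(1))

  # noise-free signal per presentation index: samples x scalp x np
  base <- .baseWaveform(times, montage)
  sig <- array(rep(base, np), c(ns, nScalp, np))
  for (j in seq_along(config$effects)) {
    e <- config$effects[[j]]
    w <- .spatialWeights(montage, e$centerChannel, e$spatialFwhmMm)
    tw <- .timeWindow(times, e$windowMs, e$rampMs)
    g <- repetitionDynamics(e$dynamics, np, e$tau)
    shape <- outer(tw, w)                   # samples x scalp
    for (r in seq_len(np))
      sig[, , r] <- sig[, , r] + e$sign * amps[j] * g[r] * shape
  }

  trials <- expand.grid(presentation = seq_len(np), object = seq_len(no),
                        block = seq_len(nb))[, 3:1]
  trials <- trials[order(trials$block, trials$object,
                         trials$presentation), ]
  rownames(trials) <- NULL
  trials$subject <- as.integer(subjectId)
  within <- (trials$object - 1) * np + trials$presentation - 1
  blockLenMs <- no * np * config$soaMs
  trials$onset <- within * config$soaMs +
    (trials$block - 1) * (blockLenMs + 20000)
  trials <- trials[c("subject", "block", "object", "presentation", "onset")]

  arr <- array(0, c(ns, nch, ntr))
  if (config$noiseSd > 0) {
    U <- .noiseChol(montage, config$noiseSpatialCorrMm)
    len <- ns + .fftPad(ns, 0L, ns)         # FFT-friendly length, truncated
    f <- (seq_len(len) - 1) / len * fs
    f <- pmin(f, fs - f)
    mag <- .butterMag(f, config$noiseBandHz, fs, 4)
    mag <- mag / sqrt(mean(mag^2))          # unit variance after shaping
    for (b in seq_len(nb)) {                # chunk by block to bound memory
      ntrb <- no * np
      white <- matrix(rnorm(len * nch * ntrb), len)
      shaped <- .applyRealSpectrum(white, mag)[seq_len(ns), , drop = FALSE]
      x <- array(shaped, c(ns, nch, ntrb))
      mixed <- crossprod(U, matrix(aperm(x, c(2, 1, 3)), nch))
      arr[, , (b - 1) * ntrb + seq_len(ntrb)] <-
        aperm(array(mixed, c(nch, ns, ntrb)), c(2, 1, 3)) * config$noiseSd
    }
  }
  for (r in seq_len(np)) {
    idx <- which(trials$presentation == r)
    arr[, seq_len(nScalp), idx] <-
      arr[, seq_len(nScalp), idx] + as.vector(sig[, , r])
  }
  data <- aperm(arr, c(3, 2, 1))            # trials x channels x samples
  new("EpochSet", data = data, trials = trials, times = times,
      samplingRate = fs, montage = montage,
      metadata = list(seed = config$seed, subjectId = subjectId,
                      effectAmplitudes = amps, config = unclass(config)))
}

#' Simulate all subjects of a study
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param montage a \linkS4class{Montage}.
#' @return list of \linkS4class{EpochSet}, one per subject.
#' @export
simulateStudy <- function(config, montage = makeDefaultMontage()) {
  lapply(seq_len(config$nSubjects), simulateSubject, config = config,
         montage = montage)
}

#' Inject high-amplitude artifacts into random trials
#'
#' Adds a short transient exceeding the given magnitude on one randomly
#' chosen channel of exactly \code{round(fraction * nTrials)} trials; used
#' to exercise the threshold rejection rule.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param fraction proportion of trials to corrupt, in [0, 1].
#' @param magnitudeUv transient magnitude in microvolts; must exceed 75
#'   (the rejection threshold), otherwise an error.
#' @param seed RNG seed for the choice of trials/channels.
#' @return list with elements \code{epochs} (corrupted copy) and
#'   \code{indices} (sorted corrupted trial indices).
#' @export
injectArtifacts <- function(epochs, fraction, magnitudeUv, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (magnitudeUv <= 75)
    stop("magnitudeUv must exceed 75 microvolts to trigger rejection")
  n <- nTrials(epochs)
  ncor <- round(fraction * n)
  if (ncor == 0) return(list(epochs = epochs, indices = integer()))
  set.seed(as.integer(seed))
  idx <- sort(sample.int(n, ncor))
  d <- dim(epochs@data)
  tt <- seq_len(d[3])
  dat <- epochs@data
  for (i in idx) {
    ch <- sample.int(d[2], 1L)
    tc <- sample.int(d[3], 1L)
    pulse <- 1.1 * magnitudeUv * exp(-(tt - tc)^2 / (2 * 2.5^2))
    s <- sign(dat[i, ch, tc])
    if (s == 0) s <- 1
    dat[i, ch, ] <- dat[i, ch, ] + s * pulse
  }
  epochs@data <- dat
  list(epochs = epochs, indices = idx)
}

#' Ground-truth space-time mask of the simulated effects
#'
#' A voxel is TRUE iff it lies inside the scalp mask, within the
#' half-maximum spatial footprint of at least one effect, and within that
#' effect's time window; the target for recovery tests.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param grid a \linkS4class{ScalpGrid}.
#' @param times frame times in ms (default: the 50-500 ms analysis window
#'   at the configured sampling rate).
#' @return logical array n x n x T.
#' @export
groundTruthMask <- function(config, grid, times = NULL) {
  if (is.null(times))
    times <- seq(50, 500, by = 1000 / config$samplingRate)
  n <- grid@n
  px <- pixelCentres(grid)
  X <- matrix(px, n, n)
  Y <- matrix(px, n, n, byrow = TRUE)
  out <- array(FALSE, c(n, n, length(times)))
  for (e in config$effects) {
    if (!e$centerChannel %in% rownames(grid@coords))
      stop(sprintf("unknown centre channel '%s'", e$centerChannel))
    cc <- grid@coords[e$centerChannel, ]
    sp <- sqrt((X - cc[1])^2 + (Y - cc[2])^2) <= e$spatialFwhmMm / 2
    sp <- sp & grid@mask
    tm <- times >= e$windowMs[1] & times <= e$windowMs[2]
    if (any(sp) && any(tm))
      out[, , tm] <- out[, , tm] | as.vector(sp)
  }
  out
}
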
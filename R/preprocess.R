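# Preprocessing: epochs -> the 24 per-subject condition-mean ERPs.
# Fixed stage order (enforced by preprocess()): band-pass filter ->
# common-average re-reference -> baseline correction -> exclusion of trials
# near distractor-target events -> threshold artifact rejection -> averaging.

#' Preprocessing configuration
#'
#' @param bandHz band-pass edges in Hz.
#' @param rolloffDbPerOctave stop-band slope per band edge; 24 dB/octave
#'   corresponds to a 4th-order Butterworth section per edge.
#' @param baselineWindowMs window whose mean is subtracted per trial and
#'   channel.
#' @param rejectThresholdUv absolute amplitude threshold; a trial is
#'   rejected iff any EEG or EOG channel exceeds it at any sample.
#' @param targetExclusionMs trials with onset within this horizon after a
#'   distractor-target event are excluded.
#' @param padSec reflective padding used when filtering epoched data.
#' @param rejectAfterBaseline whether the threshold is applied to the
#'   filtered, baseline-corrected values (recorded in the output metadata).
#' @return an object of class "PreprocConfig".
#' @export
preprocConfig <- function(bandHz = c(1, 30), rolloffDbPerOctave = 24,
                          baselineWindowMs = c(-100, 0),
                          rejectThresholdUv = 75, targetExclusionMs = 800,
                          padSec = 1, rejectAfterBaseline = TRUE) {
  stopifnot(bandHz[1] < bandHz[2], rejectThresholdUv > 0)
  structure(list(bandHz = bandHz,
                 rolloffDbPerOctave = rolloffDbPerOctave,
                 baselineWindowMs = baselineWindowMs,
                 rejectThresholdUv = rejectThresholdUv,
                 targetExclusionMs = targetExclusionMs, padSec = padSec,
                 rejectAfterBaseline = rejectAfterBaseline),
            class = "PreprocConfig")
}

.subsetEpochs <- function(epochs, keep) {
  epochs@data <- epochs@data[keep, , , drop = FALSE]
  epochs@trials <- epochs@trials[keep, , drop = FALSE]
  rownames(epochs@trials) <- NULL
  epochs
}

#' Zero-phase band-pass filter
#'
#' Applies the squared magnitude of a Butterworth band-pass (a 4th-order
#' section per band edge at the default 24 dB/octave) to every trial and
#' channel with zero phase, i.e. the magnitude response of forward-backward
#' filtering, with odd reflective padding at the epoch edges.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param config a \code{\link{preprocConfig}}.
#' @return The filtered \linkS4class{EpochSet}.
#' @export
bandpassFilter <- function(epochs, config = preprocConfig()) {
  fs <- epochs@samplingRate
  order <- round(config$rolloffDbPerOctave / 6)
  d <- dim(epochs@data)
  mat <- matrix(aperm(epochs@data, c(3, 1, 2)), d[3])
  out <- .zeroPhaseBandpass(mat, config$bandHz, fs, order, config$padSec)
  epochs@data <- aperm(array(out, c(d[3], d[1], d[2])), c(2, 3, 1))
  epochs@metadata$filter <- list(bandHz = config$bandHz, order = order,
                                 zeroPhase = TRUE)
  epochs
}

#' Re-reference to the common average
#'
#' Subtracts, at every trial and sample, the mean over scalp channels from
#' every scalp channel; EOG channels are left untouched and excluded from
#' the average.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @return The re-referenced \linkS4class{EpochSet}.
#' @export
rereferenceCommonAverage <- function(epochs) {
  nS <- length(epochs@montage@labels)
  if (nS < 2) stop("at least two scalp channels are required")
  d <- dim(epochs@data)
  dat <- epochs@data
  sub <- dat[, seq_len(nS), , drop = FALSE]
  avg <- colMeans(matrix(aperm(sub, c(2, 1, 3)), nS))  # trial x sample
  dat[, seq_len(nS), ] <- sub -
    aperm(array(avg, c(d[1], d[3], nS)), c(1, 3, 2))
  epochs@data <- dat
  epochs@metadata$reference <- "common average (scalp channels)"
  epochs
}

#' Baseline correction
#'
#' Subtracts, per trial and channel, the mean over the baseline window.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param windowMs baseline window in ms.
#' @return The corrected \linkS4class{EpochSet}.
#' @export
baselineCorrect <- function(epochs, windowMs = c(-100, 0)) {
  idx <- which(epochs@times >= windowMs[1] & epochs@times <= windowMs[2])
  if (!length(idx)) stop("baseline window contains no samples")
  d <- dim(epochs@data)
  bl <- rowMeans(matrix(epochs@data[, , idx, drop = FALSE],
                        d[1] * d[2]))                  # trial-channel means
  epochs@data <- epochs@data - as.vector(bl)
  epochs@metadata$baseline <- windowMs
  epochs
}

#' Threshold artifact rejection
#'
#' A trial is rejected iff the absolute value on any EEG or EOG channel
#' exceeds the threshold at any sample; the order of retained trials is
#' preserved.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param thresholdUv threshold in microvolts.
#' @return list with \code{retained} (\linkS4class{EpochSet}) and
#'   \code{rejected} (indices into the input trials).
#' @export
rejectArtifacts <- function(epochs, thresholdUv = 75) {
  stopifnot(thresholdUv > 0)
  n <- nTrials(epochs)
  m <- matrix(abs(epochs@data), n)
  mx <- m[cbind(seq_len(n), max.col(m, ties.method = "first"))]
  bad <- which(mx > thresholdUv)
  out <- .subsetEpochs(epochs, setdiff(seq_len(n), bad))
  out@metadata$rejected <- length(bad)
  list(retained = out, rejected = bad)
}

#' Exclude trials shortly after distractor-target events
#'
#' Drops trials whose onset lies in (t, t + horizon] for any target-event
#' time t on the same clock as the trial onsets.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param targetOnsetsMs numeric vector of event times in ms.
#' @param horizonMs exclusion horizon in ms.
#' @return The reduced \linkS4class{EpochSet}.
#' @export
excludeNearTarget <- function(epochs, targetOnsetsMs, horizonMs = 800) {
  if (!length(targetOnsetsMs)) return(epochs)
  on <- epochs@trials$onset
  bad <- vapply(on, function(o)
    any(o > targetOnsetsMs & o <= targetOnsetsMs + horizonMs), logical(1))
  .subsetEpochs(epochs, which(!bad))
}

#' Average trials by condition
#'
#' Arithmetic mean over trials per (block, presentation) cell; errors if a
#' cell is empty, naming the cell.
#'
#' @param epochs a single-subject \linkS4class{EpochSet}.
#' @param nBlocks,nPresentations expected design counts (defaulting to the
#'   maxima present).
#' @return An \linkS4class{AverageERPSet}.
#' @export
averageByCondition <- function(epochs, nBlocks = NULL,
                               nPresentations = NULL) {
  tr <- epochs@trials
  subj <- unique(tr$subject)
  if (length(subj) != 1)
    stop("averageByCondition expects a single-subject EpochSet")
  nb <- if (is.null(nBlocks)) max(tr$block) else nBlocks
  np <- if (is.null(nPresentations)) max(tr$presentation) else nPresentations
  d <- dim(epochs@data)
  means <- array(NA_real_, c(nb, np, d[2], d[3]))
  counts <- matrix(0L, nb, np)
  for (b in seq_len(nb)) for (r in seq_len(np)) {
    idx <- which(tr$block == b & tr$presentation == r)
    if (!length(idx))
      stop(sprintf("no trials in cell (block %d, presentation %d)", b, r))
    counts[b, r] <- length(idx)
    sub <- epochs@data[idx, , , drop = FALSE]
    means[b, r, , ] <- if (length(idx) == 1) sub[1, , ] else
      colMeans(sub, dims = 1)
  }
  new("AverageERPSet", means = means, counts = counts, times = epochs@times,
      samplingRate = epochs@samplingRate, montage = epochs@montage,
      subject = as.integer(subj), metadata = epochs@metadata)
}

#' Full preprocessing of one subject
#'
#' Single entry point enforcing the stage order: filter, re-reference,
#' baseline, target exclusion, threshold rejection, condition averaging.
#'
#' @param epochs a single-subject \linkS4class{EpochSet}.
#' @param config a \code{\link{preprocConfig}}.
#' @param targetOnsetsMs optional distractor-target event times (ms).
#' @return An \linkS4class{AverageERPSet}; its metadata records the filter,
#'   reference, rejection count and the threshold-ordering choice.
#' @export
preprocess <- function(epochs, config = preprocConfig(),
                       targetOnsetsMs = NULL) {
  rawRej <- NULL
  if (!config$rejectAfterBaseline) {
    r0 <- rejectArtifacts(epochs, config$rejectThresholdUv)
    epochs <- r0$retained
    rawRej <- r0$rejected
  }
  x <- bandpassFilter(epochs, config)
  x <- rereferenceCommonAverage(x)
  x <- baselineCorrect(x, config$baselineWindowMs)
  if (!is.null(targetOnsetsMs))
    x <- excludeNearTarget(x, targetOnsetsMs, config$targetExclusionMs)
  rej <- if (config$rejectAfterBaseline)
    rejectArtifacts(x, config$rejectThresholdUv)
  else list(retained = x, rejected = rawRej)
  out <- averageByCondition(rej$retained)
  out@metadata$rejectionRule <- list(
    thresholdUv = config$rejectThresholdUv,
    appliedTo = if (config$rejectAfterBaseline)
      "filtered, re-referenced, baseline-corrected values" else "raw values",
    nRejected = length(rej$rejected))
  out
}
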
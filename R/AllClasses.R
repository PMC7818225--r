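#' @import methods
#' @importFrom stats approx cor fft median mvfft pf pnorm pt qf qnorm
#'   quantile rnorm runif sd toeplitz var
#' @importFrom grDevices png dev.off
#' @importFrom graphics image hist
NULL

#' Electrode montage
#'
#' Channel labels and idealized spherical (unit-radius, head-centred)
#' electrode positions, plus the labels of the EOG channels used for artifact
#' rejection only (never interpolated onto the scalp map).
#'
#' Coordinate convention: x points to the right ear, y to the nasion, z to
#' the vertex; all scalp positions lie on the unit sphere.
#'
#' @slot labels character vector of scalp channel names.
#' @slot positions numeric matrix (channels x 3) of unit-sphere coordinates;
#'   row names equal \code{labels}.
#' @slot eogLabels character vector of EOG channel names.
#' @export
setClass("Montage",
  representation(labels = "character", positions = "matrix",
                 eogLabels = "character"))

setValidity("Montage", function(object) {
  msg <- NULL
  if (anyDuplicated(c(object@labels, object@eogLabels)))
    msg <- c(msg, "channel labels must be unique")
  if (nrow(object@positions) != length(object@labels))
    msg <- c(msg, "one position row per scalp channel required")
  nrm <- sqrt(rowSums(object@positions^2))
  if (any(abs(nrm - 1) > 1e-6))
    msg <- c(msg, "scalp positions must have unit norm (tolerance 1e-6)")
  if (is.null(msg)) TRUE else msg
})

#' Set of epoched EEG trials for one or more subjects
#'
#' @slot data numeric array, trials x channels x samples, in microvolts.
#'   Channels are the montage scalp channels followed by the EOG channels.
#' @slot trials data.frame with one row per trial: subject, block, object,
#'   presentation (1..n), and onset (ms on the recording clock).
#' @slot times numeric vector of sample times in ms relative to stimulus
#'   onset.
#' @slot samplingRate sampling rate in Hz.
#' @slot montage the \linkS4class{Montage} the channels refer to.
#' @slot metadata free-form list (seed, config echo, processing log).
#' @export
setClass("EpochSet",
  representation(data = "array", trials = "data.frame", times = "numeric",
                 samplingRate = "numeric", montage = "Montage",
                 metadata = "list"))

setValidity("EpochSet", function(object) {
  msg <- NULL
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a trials x channels x samples array")
  nchan <- length(object@montage@labels) + length(object@montage@eogLabels)
  if (d[2] != nchan)
    msg <- c(msg, "channel count must match montage (scalp + EOG)")
  if (d[3] != length(object@times))
    msg <- c(msg, "sample count must match the time axis")
  if (d[1] != nrow(object@trials))
    msg <- c(msg, "one trial row per epoch required")
  if (nrow(object@trials) &&
      any(object@trials$presentation < 1L))
    msg <- c(msg, "presentation indices must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Per-subject condition-mean ERPs
#'
#' The 24 mean ERPs (4 blocks x 6 presentation indices) that enter the
#' single-subject GLM, together with the retained-trial count per cell.
#'
#' @slot means numeric array, blocks x presentations x channels x samples.
#' @slot counts integer matrix, blocks x presentations, of trials averaged
#'   per cell.
#' @slot times,samplingRate,montage as in \linkS4class{EpochSet}.
#' @slot subject integer subject identifier.
#' @slot metadata processing log (filter band, rejection rule and ordering,
#'   rejected-trial count).
#' @export
setClass("AverageERPSet",
  representation(means = "array", counts = "matrix", times = "numeric",
                 samplingRate = "numeric", montage = "Montage",
                 subject = "integer", metadata = "list"))

setValidity("AverageERPSet", function(object) {
  d <- dim(object@means)
  msg <- NULL
  if (length(d) != 4L)
    return("means must be blocks x presentations x channels x samples")
  if (!all(d[1:2] == dim(object@counts)))
    msg <- c(msg, "counts must be blocks x presentations")
  if (any(object@counts < 1L))
    msg <- c(msg, "every condition cell must contain at least one trial")
  if (d[4] != length(object@times))
    msg <- c(msg, "sample count must match the time axis")
  if (is.null(msg)) TRUE else msg
})

#' Scalp pixel grid
#'
#' The square pixel grid all scalp maps are interpolated onto, with the
#' azimuthal-equidistant projection of the montage, the Delaunay-derived
#' barycentric interpolation weights, and the in-hull scalp mask.
#'
#' @slot n grid side length in pixels (n x n).
#' @slot pixelSizeMm pixel pitch in mm.
#' @slot rimMm planar radius the 90-degree (equatorial) circle projects to.
#' @slot headRadiusMm nominal head radius used when reporting scalp-arc
#'   distances.
#' @slot montage source montage.
#' @slot coords projected 2D electrode coordinates in mm (channels x 2).
#' @slot mask logical n x n matrix, TRUE inside the interpolation hull.
#' @slot weights dense (n*n) x channels barycentric weight matrix; rows of
#'   out-of-hull pixels are zero.
#' @slot triangles integer matrix of Delaunay triangle vertex indices.
#' @export
setClass("ScalpGrid",
  representation(n = "integer", pixelSizeMm = "numeric", rimMm = "numeric",
                 headRadiusMm = "numeric", montage = "Montage",
                 coords = "matrix", mask = "matrix", weights = "matrix",
                 triangles = "matrix"))

setValidity("ScalpGrid", function(object) {
  msg <- NULL
  if (!all(dim(object@mask) == object@n))
    msg <- c(msg, "mask must be n x n")
  if (nrow(object@coords) != length(object@montage@labels))
    msg <- c(msg, "one projected coordinate per scalp channel required")
  half <- object@n * object@pixelSizeMm / 2
  if (any(abs(object@coords) > half))
    msg <- c(msg, "all projected electrodes must fall inside the grid")
  if (is.null(msg)) TRUE else msg
})

#' Scalp-by-time image volume
#'
#' A 3D image (pixel x pixel x time) of interpolated scalp potentials in
#' microvolts; voxels outside the scalp mask are NA in every frame.
#'
#' @slot values numeric n x n x T array.
#' @slot times frame times in ms.
#' @slot grid the \linkS4class{ScalpGrid} the volume lives on.
#' @slot provenance list describing what the volume is (subject, block,
#'   presentation, or derived statistic) and the smoothing applied.
#' @export
setClass("ScalpTimeVolume",
  representation(values = "array", times = "numeric", grid = "ScalpGrid",
                 provenance = "list"))

setValidity("ScalpTimeVolume", function(object) {
  d <- dim(object@values)
  msg <- NULL
  if (length(d) != 3L || d[1] != object@grid@n || d[2] != object@grid@n)
    msg <- c(msg, "values must be n x n x T on the grid")
  else if (d[3] != length(object@times))
    msg <- c(msg, "frame count must match the time axis")
  else {
    nafrm <- is.na(object@values[, , 1, drop = TRUE])
    if (!identical(unname(nafrm), unname(!object@grid@mask)))
      msg <- c(msg, "NA pattern must equal the grid scalp mask")
  }
  if (is.null(msg)) TRUE else msg
})

#' Single-subject voxelwise GLM fit
#'
#' @slot betas coefficient matrix, parameters x voxels.
#' @slot rss residual sum of squares per voxel.
#' @slot n number of data points per voxel (24 condition means).
#' @slot k number of estimated parameters (8 regression columns; the error
#'   variance is not counted, and k is identical across the three models).
#' @slot model model tag: "exponential", "linear" or "chdet".
#' @slot tau exponential decay constant in presentation units (NA otherwise).
#' @slot subject integer subject identifier.
#' @slot design the design matrix used.
#' @export
setClass("GLMFit",
  representation(betas = "matrix", rss = "numeric", n = "integer",
                 k = "integer", model = "character", tau = "numeric",
                 subject = "integer", design = "matrix"))

setValidity("GLMFit", function(object) {
  msg <- NULL
  if (ncol(object@betas) != length(object@rss))
    msg <- c(msg, "betas and rss must cover the same voxels")
  if (any(object@rss < -1e-12))
    msg <- c(msg, "rss must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Group statistical parametric map
#'
#' Voxelwise one-sample F statistics over subjects (F = t^2, df = (1, S-1))
#' with their equivalent Z values, stored over the in-mask voxels of a
#' scalp-by-time volume.
#'
#' @slot F,Z numeric vectors over in-mask voxels (Inf-F voxels carry Z = Inf
#'   and are excluded from thresholding).
#' @slot df numeric length-2 vector (df1, df2).
#' @slot mean group mean map over in-mask voxels.
#' @slot nSubjects number of subjects entering the test.
#' @slot maskDim dimensions of the full volume, c(n, n, T).
#' @slot maskIdx linear indices of in-mask voxels in the full volume.
#' @slot times frame times in ms.
#' @export
setClass("SPMMap",
  representation(F = "numeric", Z = "numeric", df = "numeric",
                 mean = "numeric", nSubjects = "integer",
                 maskDim = "integer", maskIdx = "integer",
                 times = "numeric"))

setValidity("SPMMap", function(object) {
  msg <- NULL
  if (length(object@F) != length(object@maskIdx))
    msg <- c(msg, "one F value per in-mask voxel required")
  if (any(object@F < 0, na.rm = TRUE))
    msg <- c(msg, "F must be non-negative")
  if (is.null(msg)) TRUE else msg
})
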
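#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("eogChannels", function(x) standardGeneric("eogChannels"))

#' @rdname accessors
#' @export
setGeneric("channelPositions", function(x) standardGeneric("channelPositions"))

#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname accessors
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("conditionMeans", function(x) standardGeneric("conditionMeans"))

#' @rdname accessors
#' @export
setGeneric("trialCounts", function(x) standardGeneric("trialCounts"))

#' @rdname accessors
#' @export
setGeneric("scalpMask", function(x) standardGeneric("scalpMask"))

#' @rdname accessors
#' @export
setGeneric("volumeValues", function(x) standardGeneric("volumeValues"))

#' Accessors for erpmass containers
#'
#' Small accessor functions exposing the slots of the data containers
#' without reaching into the objects directly.
#'
#' @param x an erpmass object.
#' @return The requested component: labels and positions for montages,
#'   the trial array / trial table / time axis for epoch sets, condition
#'   means and counts for averaged sets, the logical scalp mask for grids,
#'   and the raw array for volumes.
#' @name accessors
NULL

setMethod("channelLabels", "Montage", function(x) x@labels)
setMethod("channelLabels", "EpochSet", function(x)
  c(x@montage@labels, x@montage@eogLabels))
setMethod("eogChannels", "Montage", function(x) x@eogLabels)
setMethod("eogChannels", "EpochSet", function(x) x@montage@eogLabels)
setMethod("channelPositions", "Montage", function(x) x@positions)
setMethod("sampleTimes", "EpochSet", function(x) x@times)
setMethod("sampleTimes", "AverageERPSet", function(x) x@times)
setMethod("sampleTimes", "ScalpTimeVolume", function(x) x@times)
setMethod("samplingRate", "EpochSet", function(x) x@samplingRate)
setMethod("samplingRate", "AverageERPSet", function(x) x@samplingRate)
setMethod("epochData", "EpochSet", function(x) x@data)
setMethod("trialInfo", "EpochSet", function(x) x@trials)
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1])
setMethod("conditionMeans", "AverageERPSet", function(x) x@means)
setMethod("trialCounts", "AverageERPSet", function(x) x@counts)
setMethod("scalpMask", "ScalpGrid", function(x) x@mask)
setMethod("scalpMask", "ScalpTimeVolume", function(x) x@grid@mask)
setMethod("volumeValues", "ScalpTimeVolume", function(x) x@values)

setMethod("show", "Montage", function(object) {
  cat(sprintf("Montage: %d scalp channels, %d EOG channels\n",
              length(object@labels), length(object@eogLabels)))
  cat("  scalp:", paste(utils::head(object@labels, 8), collapse = " "),
      "...\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochSet: %d trials x %d channels x %d samples (%g Hz, %g..%g ms)\n",
    d[1], d[2], d[3], object@samplingRate, min(object@times),
    max(object@times)))
  if (nrow(object@trials))
    cat(sprintf("  subjects: %s; blocks: %s; presentations: %s\n",
                paste(unique(object@trials$subject), collapse = ","),
                paste(sort(unique(object@trials$block)), collapse = ","),
                paste(range(object@trials$presentation), collapse = "-")))
})

setMethod("show", "AverageERPSet", function(object) {
  d <- dim(object@means)
  cat(sprintf(
    "AverageERPSet (subject %d): %d blocks x %d presentations, %d channels x %d samples\n",
    object@subject, d[1], d[2], d[3], d[4]))
  cat(sprintf("  trials per cell: %d..%d\n", min(object@counts),
              max(object@counts)))
})

setMethod("show", "ScalpGrid", function(object) {
  cat(sprintf(
    "ScalpGrid: %dx%d pixels at %.3g mm/pixel, %d in-hull pixels\n",
    object@n, object@n, object@pixelSizeMm, sum(object@mask)))
})

setMethod("show", "ScalpTimeVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "ScalpTimeVolume: %dx%dx%d (%g..%g ms), %s\n", d[1], d[2], d[3],
    min(object@times), max(object@times),
    if (length(object@provenance))
      paste(names(object@provenance), unlist(lapply(object@provenance,
        function(v) paste(format(v), collapse = " "))),
        sep = "=", collapse = ", ")
    else "no provenance"))
})

setMethod("show", "GLMFit", function(object) {
  cat(sprintf(
    "GLMFit (subject %d, model %s): %d x %d design over %d voxels\n",
    object@subject, object@model, object@n, object@k, ncol(object@betas)))
})

setMethod("show", "SPMMap", function(object) {
  cat(sprintf(
    "SPMMap: F(%g,%g) over %d voxels, S = %d, max F = %.3f (Z = %.3f)\n",
    object@df[1], object@df[2], length(object@F), object@nSubjects,
    max(object@F[is.finite(object@F)]),
    max(object@Z[is.finite(object@Z)])))
})
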
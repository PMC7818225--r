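# Scalp-by-time image volumes: one interpolated 32x32 frame per sample of
# the 50-500 ms analysis window (226 frames at 500 Hz), smoothed with a
# separable Gaussian of FWHM [16 mm, 16 mm, 16 ms] by default.

#' Smoothing specification
#'
#' @param fwhm numeric length-3 vector, full-width at half-maximum along
#'   x (mm), y (mm) and time (ms).
#' @return an object of class "SmoothingSpec".
#' @export
smoothingSpec <- function(fwhm = c(16, 16, 16)) {
  stopifnot(length(fwhm) == 3, all(fwhm > 0))
  structure(list(fwhm = fwhm), class = "SmoothingSpec")
}

#' Build a scalp-by-time volume from one mean ERP
#'
#' Interpolates one scalp-map frame per sample of the closed analysis
#' window. At 500 Hz the default 50-500 ms window yields 226 frames.
#'
#' @param erp numeric channels x samples matrix (scalp channels in montage
#'   order; extra EOG rows are ignored) in microvolts.
#' @param times sample times of \code{erp} columns, in ms.
#' @param grid a \linkS4class{ScalpGrid}.
#' @param windowMs closed analysis window in ms; must be covered by
#'   \code{times}.
#' @param provenance optional list recorded on the volume.
#' @return A \linkS4class{ScalpTimeVolume}.
#' @export
buildVolume <- function(erp, times, grid, windowMs = c(50, 500),
                        provenance = list()) {
  if (windowMs[1] < min(times) || windowMs[2] > max(times))
    stop("analysis window lies outside the epoch time axis")
  nS <- length(grid@montage@labels)
  erp <- erp[seq_len(nS), , drop = FALSE]
  idx <- which(times >= windowMs[1] & times <= windowMs[2])
  flat <- grid@weights %*% erp[, idx, drop = FALSE]   # pixels x frames
  vals <- array(flat, c(grid@n, grid@n, length(idx)))
  vals[array(!grid@mask, dim(vals))] <- NA_real_
  new("ScalpTimeVolume", values = vals, times = times[idx], grid = grid,
      provenance = provenance)
}

#' Gaussian smoothing of a scalp-by-time volume
#'
#' Separable Gaussian convolution with sigma = FWHM / sqrt(8 ln 2) per
#' axis, expressed in voxel units from the grid pixel pitch and the frame
#' spacing. The NA region is handled by mask-weighted (normalized)
#' convolution, so every in-mask output value is a convex combination of
#' in-mask input values and the NA pattern is unchanged.
#'
#' @param vol a \linkS4class{ScalpTimeVolume}.
#' @param spec a \code{\link{smoothingSpec}}.
#' @return The smoothed \linkS4class{ScalpTimeVolume}.
#' @export
smoothVolume <- function(vol, spec = smoothingSpec()) {
  dt <- if (length(vol@times) > 1) diff(vol@times[1:2]) else 1
  sig <- spec$fwhm / c(vol@grid@pixelSizeMm, vol@grid@pixelSizeMm, dt) /
    sqrt(8 * log(2))
  mask3 <- array(vol@grid@mask, dim(vol@values))
  vol@values <- .smoothMasked(vol@values, mask3, sig)
  vol@provenance$smoothedFwhm <- spec$fwhm
  vol
}

#' Extract / insert the in-mask voxel vector of a volume
#'
#' Statistics run over in-mask voxels as flat vectors;
#' \code{volumeToVoxels} extracts them in a fixed linear order and
#' \code{voxelsToVolume} puts such a vector back into a NA-padded array.
#'
#' @param vol a \linkS4class{ScalpTimeVolume}.
#' @param x numeric vector over in-mask voxels.
#' @param grid a \linkS4class{ScalpGrid}.
#' @param nT number of frames.
#' @return \code{volumeToVoxels}: numeric vector; \code{voxelsToVolume}:
#'   numeric n x n x T array with NA outside the mask.
#' @export
volumeToVoxels <- function(vol) {
  info <- .maskInfo(vol@grid@mask, length(vol@times))
  vol@values[info$idx]
}

#' @rdname volumeToVoxels
#' @export
voxelsToVolume <- function(x, grid, nT) {
  info <- .maskInfo(grid@mask, nT)
  stopifnot(length(x) == length(info$idx))
  .voxelsToVolume(x, info)
}

#' Volumes for all condition cells of one subject
#'
#' @param averages an \linkS4class{AverageERPSet}.
#' @param grid a \linkS4class{ScalpGrid}.
#' @param windowMs analysis window.
#' @param spec a \code{\link{smoothingSpec}}, or NULL to skip smoothing.
#' @return list of \linkS4class{ScalpTimeVolume} in block-major cell order
#'   (block 1 presentations 1..6, block 2 ...), matching the GLM row order.
#' @export
buildSubjectVolumes <- function(averages, grid, windowMs = c(50, 500),
                                spec = smoothingSpec()) {
  d <- dim(averages@means)
  out <- vector("list", d[1] * d[2])
  i <- 0L
  for (b in seq_len(d[1])) for (r in seq_len(d[2])) {
    i <- i + 1L
    v <- buildVolume(matrix(averages@means[b, r, , ], d[3], d[4]),
                     averages@times, grid, windowMs,
                     provenance = list(subject = averages@subject,
                                       block = b, presentation = r))
    if (!is.null(spec)) v <- smoothVolume(v, spec)
    out[[i]] <- v
  }
  out
}

#' Stack subject volumes into the GLM response matrix
#'
#' @param volumes list of 24 cell volumes from
#'   \code{\link{buildSubjectVolumes}}.
#' @return numeric matrix, cells x in-mask voxels, rows in block-major
#'   order.
#' @export
volumesToMatrix <- function(volumes) {
  t(vapply(volumes, volumeToVoxels,
           numeric(sum(volumes[[1]]@grid@mask) * length(volumes[[1]]@times))))
}

#' Batched voxel matrix for one subject
#'
#' Equivalent to \code{\link{buildSubjectVolumes}} followed by
#' \code{\link{volumesToMatrix}}, but interpolates and smooths all 24 cell
#' volumes in batched matrix operations (the smoothed mask is computed
#' once); used on the hot path of multi-dataset runs.
#'
#' @param averages an \linkS4class{AverageERPSet}.
#' @param grid a \linkS4class{ScalpGrid}.
#' @param windowMs analysis window in ms.
#' @param spec a \code{\link{smoothingSpec}} or NULL to skip smoothing.
#' @return numeric matrix, cells x in-mask voxels, block-major row order.
#' @export
subjectVoxelMatrix <- function(averages, grid, windowMs = c(50, 500),
                               spec = smoothingSpec()) {
  d <- dim(averages@means)
  times <- averages@times
  if (windowMs[1] < min(times) || windowMs[2] > max(times))
    stop("analysis window lies outside the epoch time axis")
  idx <- which(times >= windowMs[1] & times <= windowMs[2])
  nS <- length(grid@montage@labels)
  nT <- length(idx)
  ncell <- d[1] * d[2]
  sub <- averages@means[, , seq_len(nS), idx, drop = FALSE]
  E <- matrix(aperm(sub, c(3, 4, 2, 1)), nS)   # ch x (frames*cells)
  arr <- array(grid@weights %*% E, c(grid@n, grid@n, nT, ncell))
  if (!is.null(spec)) {
    dt <- if (nT > 1) diff(times[idx][1:2]) else 1
    sig <- spec$fwhm / c(grid@pixelSizeMm, grid@pixelSizeMm, dt) /
      sqrt(8 * log(2))
    out <- !grid@mask
    arr[c(out)] <- 0
    M <- array(as.numeric(grid@mask), c(grid@n, grid@n, nT))
    for (ax in 1:3) {
      k <- .gaussKernel(sig[ax])
      arr <- .convAxis(arr, k, ax)
      M <- .convAxis(M, k, ax)
    }
    arr <- arr / as.vector(M)
  }
  info <- .maskInfo(grid@mask, nT)
  t(matrix(arr, grid@n * grid@n * nT, ncell)[info$idx, , drop = FALSE])
}

#' Save / load a volume in the native array container
#'
#' \code{saveVolume} writes the raw values as little-endian 64-bit floats
#' plus a JSON sidecar (dimensions, times, grid geometry, provenance);
#' \code{loadVolume} restores them bit-identically onto a matching grid.
#'
#' @param vol a \linkS4class{ScalpTimeVolume}.
#' @param prefix path prefix; \code{.f64} and \code{.json} are appended.
#' @param grid the \linkS4class{ScalpGrid} the volume was built on.
#' @return \code{saveVolume}: the prefix, invisibly; \code{loadVolume}: a
#'   \linkS4class{ScalpTimeVolume}.
#' @export
saveVolume <- function(vol, prefix) {
  con <- file(paste0(prefix, ".f64"), "wb")
  writeBin(as.vector(vol@values), con, size = 8, endian = "little")
  close(con)
  meta <- list(dim = dim(vol@values), times = vol@times,
               n = vol@grid@n, pixelSizeMm = vol@grid@pixelSizeMm,
               rimMm = vol@grid@rimMm, provenance = vol@provenance)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname saveVolume
#' @export
loadVolume <- function(prefix, grid) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  if (meta$n != grid@n || abs(meta$pixelSizeMm - grid@pixelSizeMm) > 1e-12)
    stop("stored volume geometry does not match the supplied grid")
  con <- file(paste0(prefix, ".f64"), "rb")
  vals <- readBin(con, "double", n = prod(meta$dim), size = 8,
                  endian = "little")
  close(con)
  prov <- meta$provenance
  new("ScalpTimeVolume", values = array(vals, meta$dim),
      times = as.numeric(meta$times), grid = grid,
      provenance = if (is.null(prov)) list() else as.list(prov))
}

#' Export a volume as NIfTI-1
#'
#' Axes are (x, y, time); the header pixel dimensions carry the pixel pitch
#' in mm and the frame spacing in ms, and out-of-mask voxels are NaN.
#'
#' @param vol a \linkS4class{ScalpTimeVolume}.
#' @param path output file (".nii" or ".nii.gz").
#' @return \code{path}, invisibly.
#' @export
writeVolumeNifti <- function(vol, path) {
  dt <- if (length(vol@times) > 1) diff(vol@times[1:2]) else 1
  img <- RNifti::asNifti(vol@values)
  RNifti::pixdim(img) <- c(vol@grid@pixelSizeMm, vol@grid@pixelSizeMm, dt)
  RNifti::writeNifti(img, path)
  invisible(path)
}
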
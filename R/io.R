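# Plain-file containers: per-subject little-endian float32 arrays with a
# JSON sidecar (plus the montage as tab-separated text), so datasets can
# be exchanged without any R-specific serialization.

#' Write / read an epoch container directory
#'
#' One \code{epochs_s<id>.f32} file per subject (trials x channels x
#' samples, column-major, little-endian 32-bit float, microvolts), the
#' montage as \code{montage.tsv}, and a \code{epochs.json} sidecar holding
#' labels, trial tables, time axis, sampling rate, seed and config echo.
#' Note the 32-bit storage rounds values to single precision.
#'
#' @param epochs an \linkS4class{EpochSet} or list of them (one per
#'   subject).
#' @param dir container directory (created if needed).
#' @return \code{writeEpochSet}: \code{dir}, invisibly;
#'   \code{readEpochSet}: list of \linkS4class{EpochSet}.
#' @export
writeEpochSet <- function(epochs, dir) {
  if (is(epochs, "EpochSet")) epochs <- list(epochs)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMontage(epochs[[1]]@montage, file.path(dir, "montage.tsv"))
  subjects <- lapply(epochs, function(e) {
    id <- unique(e@trials$subject)
    stopifnot(length(id) == 1)
    fn <- sprintf("epochs_s%03d.f32", id)
    con <- file(file.path(dir, fn), "wb")
    writeBin(as.vector(e@data), con, size = 4, endian = "little")
    close(con)
    list(id = id, file = fn, dim = dim(e@data), trials = e@trials,
         metadata = e@metadata[setdiff(names(e@metadata), "config")])
  })
  meta <- list(subjects = subjects,
               times = epochs[[1]]@times,
               samplingRate = epochs[[1]]@samplingRate,
               config = epochs[[1]]@metadata$config)
  jsonlite::write_json(meta, file.path(dir, "epochs.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeEpochSet
#' @export
readEpochSet <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "epochs.json"),
                              simplifyVector = TRUE)
  montage <- readMontage(file.path(dir, "montage.tsv"))
  n <- if (is.data.frame(meta$subjects)) nrow(meta$subjects) else
    length(meta$subjects)
  lapply(seq_len(n), function(i) {
    s <- if (is.data.frame(meta$subjects)) {
      list(file = meta$subjects$file[i],
           dim = unlist(meta$subjects$dim[i]),
           trials = meta$subjects$trials[[i]],
           metadata = meta$subjects$metadata[i])
    } else meta$subjects[[i]]
    con <- file(file.path(dir, s$file), "rb")
    vals <- readBin(con, "double", n = prod(s$dim), size = 4,
                    endian = "little")
    close(con)
    new("EpochSet", data = array(vals, s$dim),
        trials = as.data.frame(s$trials), times = meta$times,
        samplingRate = meta$samplingRate, montage = montage,
        metadata = list(config = meta$config))
  })
}

#' Write / read a per-subject average-ERP container
#'
#' The 4 x 6 x channels x samples means as little-endian 64-bit floats
#' plus a JSON sidecar with counts and geometry.
#'
#' @param averages an \linkS4class{AverageERPSet}.
#' @param prefix path prefix (\code{.f64}/\code{.json} appended).
#' @param montage the montage the averages refer to.
#' @return \code{writeAverageSet}: prefix invisibly; \code{readAverageSet}:
#'   an \linkS4class{AverageERPSet}.
#' @export
writeAverageSet <- function(averages, prefix) {
  con <- file(paste0(prefix, ".f64"), "wb")
  writeBin(as.vector(averages@means), con, size = 8, endian = "little")
  close(con)
  meta <- list(dim = dim(averages@means), counts = averages@counts,
               times = averages@times, samplingRate = averages@samplingRate,
               subject = averages@subject,
               metadata = averages@metadata[
                 setdiff(names(averages@metadata), "config")])
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname writeAverageSet
#' @export
readAverageSet <- function(prefix, montage) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  con <- file(paste0(prefix, ".f64"), "rb")
  vals <- readBin(con, "double", n = prod(meta$dim), size = 8,
                  endian = "little")
  close(con)
  new("AverageERPSet", means = array(vals, meta$dim),
      counts = matrix(as.integer(meta$counts), nrow(meta$counts)),
      times = meta$times, samplingRate = meta$samplingRate,
      montage = montage, subject = as.integer(meta$subject),
      metadata = as.list(meta$metadata))
}
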
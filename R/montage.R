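# Idealized spherical 10-20 montage construction.
#
# The 61-channel layout is built on the unit sphere from the classical
# angular scheme: the outer ring (10% line) sits at 72 degrees inclination
# from the vertex with electrodes every 18 degrees of azimuth; midline
# electrodes step in 18-degree increments between Fpz, Cz and Oz; the inner
# rows are placed by spherical interpolation (slerp) between their ring
# endpoints and midline electrode.

.slerp <- function(u, v, t) {
  w <- sum(u * v)
  w <- min(max(w, -1), 1)
  om <- acos(w)
  if (om < 1e-12) return(u)
  (sin((1 - t) * om) * u + sin(t * om) * v) / sin(om)
}

.sph <- function(inclDeg, azDeg) {
  i <- inclDeg * pi / 180
  a <- azDeg * pi / 180
  c(sin(i) * sin(a), sin(i) * cos(a), cos(i))
}

#' Default 61-channel montage
#'
#' Builds the modified international 10-20 layout with 61 scalp channels
#' (AF7, Fp1, Fpz, ..., O1, Oz, O2) on idealized unit-sphere positions,
#' plus four EOG channel labels (two vertical, two horizontal) used for
#' artifact rejection only.
#'
#' @return A \linkS4class{Montage}.
#' @examples
#' m <- makeDefaultMontage()
#' channelLabels(m)[1:5]
#' @export
makeDefaultMontage <- function() {
  pos <- list()
  # outer ring at 72 deg inclination; azimuth from the front midline,
  # positive to the right
  ringR <- c(Fpz = 0, Fp2 = 18, AF8 = 36, F8 = 54, FT8 = 72, T8 = 90,
             TP8 = 108, P8 = 126, PO8 = 144, O2 = 162, Oz = 180)
  ringL <- c(Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90, TP7 = 108,
             P7 = 126, PO7 = 144, O1 = 162)
  for (nm in names(ringR)) pos[[nm]] <- .sph(72, ringR[[nm]])
  for (nm in names(ringL)) pos[[nm]] <- .sph(72, -ringL[[nm]])
  # midline between Fpz (front) and Oz (back) in 18-degree steps
  mid <- list(AFz = 54, Fz = 36, FCz = 18, Cz = 0,
              CPz = -18, Pz = -36, POz = -54)
  for (nm in names(mid)) {
    i <- mid[[nm]]
    pos[[nm]] <- if (i >= 0) .sph(i, 0) else .sph(-i, 180)
  }
  # inner rows: slerp between the lateral ring electrode and the midline
  rows <- list(
    F  = list(left = "F7",  mids = c("F5", "F3", "F1"),  centre = "Fz",
              rights = c("F2", "F4", "F6"),  right = "F8"),
    FC = list(left = "FT7", mids = c("FC5", "FC3", "FC1"), centre = "FCz",
              rights = c("FC2", "FC4", "FC6"), right = "FT8"),
    C  = list(left = "T7",  mids = c("C5", "C3", "C1"),  centre = "Cz",
              rights = c("C2", "C4", "C6"),  right = "T8"),
    CP = list(left = "TP7", mids = c("CP5", "CP3", "CP1"), centre = "CPz",
              rights = c("CP2", "CP4", "CP6"), right = "TP8"),
    P  = list(left = "P7",  mids = c("P5", "P3", "P1"),  centre = "Pz",
              rights = c("P2", "P4", "P6"),  right = "P8"),
    AF = list(left = "AF7", mids = "AF3", centre = "AFz",
              rights = "AF4", right = "AF8"),
    PO = list(left = "PO7", mids = "PO3", centre = "POz",
              rights = "PO4", right = "PO8"))
  for (rw in rows) {
    kl <- length(rw$mids)
    for (j in seq_len(kl))
      pos[[rw$mids[j]]] <- .slerp(pos[[rw$left]], pos[[rw$centre]],
                                  j / (kl + 1))
    for (j in seq_len(kl))
      pos[[rw$rights[j]]] <- .slerp(pos[[rw$centre]], pos[[rw$right]],
                                    j / (kl + 1))
  }
  labels <- c("AF7", "Fp1", "Fpz", "Fp2", "AF8", "AF3", "AFz", "AF4",
              "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
              "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
              "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
              "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
              "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
              "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2")
  P <- t(vapply(labels, function(nm) pos[[nm]], numeric(3)))
  P <- P / sqrt(rowSums(P^2))
  dimnames(P) <- list(labels, c("x", "y", "z"))
  new("Montage", labels = labels, positions = P,
      eogLabels = c("VEOGU", "VEOGL", "HEOGL", "HEOGR"))
}

#' Read / write a montage file
#'
#' Tab-separated text with columns label/x/y/z, one row per scalp channel.
#' Comment lines start with '#'; a comment of the form \code{# eog: A B C D}
#' carries the EOG channel labels.
#'
#' @param path file path.
#' @param montage a \linkS4class{Montage} (for writing).
#' @return \code{readMontage} returns a \linkS4class{Montage};
#'   \code{writeMontage} returns \code{path} invisibly.
#' @examples
#' m <- readMontage(system.file("extdata", "montage61.tsv",
#'                              package = "erpmass"))
#' length(channelLabels(m))
#' @export
readMontage <- function(path) {
  lines <- readLines(path)
  eog <- character()
  cm <- grep("^\\s*#", lines, value = TRUE)
  hit <- grep("^\\s*#\\s*eog:", cm, value = TRUE)
  if (length(hit))
    eog <- strsplit(trimws(sub("^\\s*#\\s*eog:", "", hit[1])), "\\s+")[[1]]
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(body, "\t")
  labels <- vapply(parts, `[[`, "", 1L)
  P <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  dimnames(P) <- list(labels, c("x", "y", "z"))
  new("Montage", labels = labels, positions = P, eogLabels = eog)
}

#' @rdname readMontage
#' @export
writeMontage <- function(montage, path) {
  stopifnot(is(montage, "Montage"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# erpmass montage: label\tx\ty\tz (unit sphere)", con)
  if (length(montage@eogLabels))
    writeLines(paste("# eog:", paste(montage@eogLabels, collapse = " ")),
               con)
  writeLines(sprintf("%s\t%.17g\t%.17g\t%.17g", montage@labels,
                     montage@positions[, 1], montage@positions[, 2],
                     montage@positions[, 3]), con)
  invisible(path)
}

#' Project electrodes onto the scalp map plane
#'
#' Azimuthal-equidistant projection about the vertex: each electrode maps
#' to planar polar coordinates with radius proportional to its spherical
#' arc distance from the vertex, so arc distances from the vertex are
#' preserved up to a single global scale. The scale is set by \code{rimMm},
#' the planar radius assigned to the 90-degree (equatorial) circle, chosen
#' so that the whole montage fits inside the pixel grid.
#'
#' @param montage a \linkS4class{Montage}.
#' @param rimMm planar radius (mm) of the equatorial circle.
#' @return numeric matrix (channels x 2) of planar mm coordinates; the
#'   vertex (Cz) maps to (0, 0).
#' @export
projectElectrodes <- function(montage, rimMm = 60) {
  P <- montage@positions
  incl <- acos(pmin(pmax(P[, 3], -1), 1))      # arc from vertex, radians
  r <- rimMm * incl / (pi / 2)
  az <- atan2(P[, 1], P[, 2])                  # from front midline
  out <- cbind(x = r * sin(az), y = r * cos(az))
  out[incl < 1e-12, ] <- 0
  rownames(out) <- montage@labels
  out
}
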
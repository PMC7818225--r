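# Second-level inference: block-pooled modulator betas per subject enter a
# one-sample test per voxel (F = t^2, df = (1, S-1)); voxel-level
# family-wise error control uses the expected Euler characteristic of the
# F excursion set (random field theory), with field smoothness estimated
# from the standardized group residuals.

#' Pool the block-specific modulator betas
#'
#' Arithmetic mean of the four block modulator coefficients per voxel; the
#' per-subject summary statistic entering group inference.
#'
#' @param fit a \linkS4class{GLMFit} from \code{\link{buildDesign}} (the
#'   modulator columns are the second half of the parameters).
#' @return numeric vector over voxels.
#' @export
poolBlocks <- function(fit) {
  k <- fit@k
  rows <- (k / 2 + 1):k
  colMeans(fit@betas[rows, , drop = FALSE])
}

#' Voxelwise one-sample F test across subjects
#'
#' Per voxel, t = mean / (sd / sqrt(S)) with the sample standard deviation
#' (S - 1 denominator); F = t^2 with df = (1, S - 1), converted to an
#' equivalent Z. Voxels with zero variance get an infinite F (flagged with
#' a warning) and are excluded from thresholding.
#'
#' @param sample numeric matrix, subjects x voxels, of pooled betas.
#' @param maskDim,maskIdx,times optional volume bookkeeping stored on the
#'   map (needed for cluster extraction).
#' @return An \linkS4class{SPMMap}.
#' @export
oneSampleF <- function(sample, maskDim = dim(sample), maskIdx = integer(),
                       times = numeric()) {
  S <- nrow(sample)
  if (S < 2) stop("at least two subjects are required")
  m <- colMeans(sample)
  v <- colSums(sweep(sample, 2, m)^2) / (S - 1)
  F <- S * m^2 / v
  if (any(v == 0)) {
    warning(sprintf("%d zero-variance voxels: F set to Inf and excluded",
                    sum(v == 0)))
    F[v == 0] <- Inf
  }
  Z <- ifelse(is.finite(F), fToZ(F, c(1, S - 1)), Inf)
  if (!length(maskIdx)) maskIdx <- seq_along(F)
  new("SPMMap", F = unname(F), Z = unname(Z), df = c(1, S - 1),
      mean = unname(m), nSubjects = as.integer(S),
      maskDim = as.integer(maskDim), maskIdx = as.integer(maskIdx),
      times = as.numeric(times))
}

#' Equivalent Z statistic of an F value
#'
#' The standard-normal deviate whose upper-tail probability equals the
#' upper-tail probability of F under F(df1, df2); computed through the
#' distribution tails so extreme values (p ~ 1e-7 and beyond) stay exact.
#'
#' @param F F value(s), >= 0.
#' @param df numeric length-2 vector (df1, df2).
#' @return numeric equivalent Z value(s).
#' @examples
#' fToZ(61.2678, c(1, 16))    # 4.815
#' @export
fToZ <- function(F, df) {
  stopifnot(all(F >= 0), df[2] >= 1)
  qnorm(pf(F, df[1], df[2], lower.tail = FALSE), lower.tail = FALSE)
}

#' Estimate field smoothness from standardized residuals
#'
#' Residuals of the group model are standardized to unit variance per
#' voxel; the per-axis FWHM follows from the variance of their partial
#' derivatives (first differences within the mask):
#' fwhm = sqrt(4 ln 2 / mean(derivative^2)), in voxel units.
#'
#' @param residuals numeric matrix, subjects x in-mask voxels, of group
#'   residuals (x - mean).
#' @param maskDim c(n, n, T) dimensions of the volume.
#' @param maskIdx linear indices of in-mask voxels.
#' @return numeric length-3 vector of FWHM estimates (x, y, t) in voxels.
#' @export
estimateSmoothness <- function(residuals, maskDim, maskIdx) {
  S <- nrow(residuals)
  sdv <- sqrt(colSums(residuals^2) / (S - 1))
  std <- sweep(residuals, 2, pmax(sdv, 1e-300), "/")
  mask <- array(FALSE, maskDim)
  mask[maskIdx] <- TRUE
  fwhm <- numeric(3)
  for (ax in 1:3) {
    d <- maskDim
    take <- function(arr, drop1) {
      idx <- rep(list(quote(expr = )), 3)
      idx[[ax]] <- if (drop1) seq_len(d[ax] - 1L) else seq(2L, d[ax])
      do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    }
    pairOk <- take(mask, TRUE) & take(mask, FALSE)
    if (!any(pairOk))
      stop("mask too small to form derivatives along axis ", ax)
    acc <- 0
    for (s in seq_len(S)) {
      vol <- array(NA_real_, maskDim)
      vol[maskIdx] <- std[s, ]
      dif <- take(vol, FALSE) - take(vol, TRUE)
      acc <- acc + mean(dif[pairOk]^2)
    }
    fwhm[ax] <- sqrt(4 * log(2) / (acc / S))
  }
  fwhm
}

# Expected Euler characteristic of the excursion set of an F(1, v) field
# above threshold f, for a search region summarized by resel counts
# R = (R0, R1, R2, R3). The F(1, v) excursion set is the disjoint union of
# the two symmetric t-field excursion sets above sqrt(f), so its EC
# densities are twice the t-field densities, which are used directly.
.tECdensity <- function(u, v, d) {
  c1 <- sqrt(4 * log(2))
  base <- (1 + u^2 / v)^(-(v - 1) / 2)
  switch(d + 1L,
    pt(u, v, lower.tail = FALSE),
    c1 / (2 * pi) * base,
    c1^2 / (2 * pi)^1.5 *
      exp(lgamma((v + 1) / 2) - lgamma(v / 2)) / sqrt(v / 2) * base * u,
    c1^3 / (2 * pi)^2 * base * ((v - 1) / v * u^2 - 1))
}

#' Expected Euler characteristic for an F(1, v) field
#'
#' @param f F threshold.
#' @param df numeric (1, v); only df1 = 1 is supported (the group test is
#'   a squared one-sample t).
#' @param resels numeric length-4 vector of resel counts (R0..R3).
#' @return expected EC (approximate family-wise error probability).
#' @export
expectedEC <- function(f, df, resels) {
  if (df[1] != 1)
    stop("only df1 = 1 (one-sample t squared) is supported")
  u <- sqrt(f)
  sum(vapply(0:3, function(d)
    resels[d + 1] * 2 * .tECdensity(u, df[2], d), numeric(1)))
}

#' Resel counts of the search region
#'
#' The masked search region is summarized as a cuboid with the same
#' in-plane area and frame count (sides sqrt(A), sqrt(A), T voxels),
#' expressed in resolution elements per axis; edge and face resels are
#' included.
#'
#' @param maskDim c(n, n, T).
#' @param maskIdx in-mask linear indices.
#' @param fwhm per-axis smoothness in voxels.
#' @return numeric length-4 resel counts (R0..R3).
#' @export
reselCounts <- function(maskDim, maskIdx, fwhm) {
  nT <- maskDim[3]
  A <- length(maskIdx) / nT
  sides <- c(sqrt(A), sqrt(A), nT) / fwhm
  c(1,
    sum(sides),
    sides[1] * sides[2] + sides[1] * sides[3] + sides[2] * sides[3],
    prod(sides))
}

#' Family-wise error F threshold via random field theory
#'
#' The smallest F whose expected Euler characteristic over the search
#' region is alpha, found by bisection to 1e-6.
#'
#' @param df (1, v) degrees of freedom.
#' @param fwhm estimated per-axis smoothness in voxels.
#' @param maskDim,maskIdx search region.
#' @param alpha target voxel-level family-wise error rate.
#' @return the F threshold.
#' @export
fweThreshold <- function(df, fwhm, maskDim, maskIdx, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  resels <- reselCounts(maskDim, maskIdx, fwhm)
  lo <- 0; hi <- 10
  iter <- 0
  while (expectedEC(hi, df, resels) > alpha) {
    hi <- hi * 2
    iter <- iter + 1
    if (iter > 60 || !is.finite(expectedEC(hi, df, resels)))
      stop("expected EC does not reach alpha at these degrees of freedom ",
           "(too few subjects for RFT control over this search volume)")
  }
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (expectedEC(mid, df, resels) > alpha) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# 26-connectivity connected components over a logical 3D array
# (breadth-first with vectorized frontier expansion)
.components <- function(supra) {
  d <- dim(supra)
  lab <- array(0L, d)
  cur <- 0L
  nb <- as.matrix(expand.grid(x = -1:1, y = -1:1, t = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  for (start in which(supra)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    frontier <- start
    while (length(frontier)) {
      co <- arrayInd(frontier, d)
      found <- integer()
      for (q in seq_len(nrow(nb))) {
        pp <- co + rep(nb[q, ], each = nrow(co))
        ok <- pp[, 1] >= 1 & pp[, 1] <= d[1] & pp[, 2] >= 1 &
          pp[, 2] <= d[2] & pp[, 3] >= 1 & pp[, 3] <= d[3]
        if (!any(ok)) next
        lin <- pp[ok, 1] + (pp[ok, 2] - 1L) * d[1] +
          (pp[ok, 3] - 1L) * d[1] * d[2]
        cand <- lin[supra[lin] & lab[lin] == 0L]
        if (length(cand)) {
          lab[cand] <- cur
          found <- c(found, cand)
        }
      }
      frontier <- unique(found)
    }
  }
  lab
}

#' Cluster table of suprathreshold voxels
#'
#' Connected components (26-connectivity in x, y, t) of voxels with
#' F above threshold, reported with up to three local-maximum peaks each
#' (peaks closer than 8 mm and 8 ms to a stronger one are absorbed),
#' sorted by cluster size descending. The voxel-level FWE p of a peak is
#' the expected Euler characteristic at its F value, capped at 1.
#'
#' @param spm an \linkS4class{SPMMap} carrying maskDim/maskIdx/times.
#' @param threshold F threshold.
#' @param grid the \linkS4class{ScalpGrid} (for mm peak separation).
#' @param fwhm smoothness in voxels (for peak FWE p values); if missing,
#'   p values are NA.
#' @param maxPeaks peaks reported per cluster.
#' @param minPeakSepMm,minPeakSepMs separation rule for distinct peaks.
#' @return data.frame with columns activation, size, latency_ms, p_fwe,
#'   F, Z (one row per peak).
#' @export
extractClusters <- function(spm, threshold, grid, fwhm = NULL,
                            maxPeaks = 3L, minPeakSepMm = 8,
                            minPeakSepMs = 8) {
  stopifnot(is.finite(threshold))
  empty <- data.frame(activation = integer(), size = integer(),
                      latency_ms = numeric(), p_fwe = numeric(),
                      F = numeric(), Z = numeric())
  Fvol <- .voxelsToVolume(ifelse(is.finite(spm@F), spm@F, NA_real_),
                          list(dim = spm@maskDim, idx = spm@maskIdx))
  supra <- !is.na(Fvol) & Fvol > threshold
  if (!any(supra)) return(empty)
  lab <- .components(supra)
  resels <- if (!is.null(fwhm))
    reselCounts(spm@maskDim, spm@maskIdx, fwhm) else NULL
  px <- pixelCentres(grid)
  dtms <- if (length(spm@times) > 1) diff(spm@times[1:2]) else 1
  rows <- list()
  sizes <- tabulate(lab[lab > 0])
  ord <- order(sizes, decreasing = TRUE)
  act <- 0L
  for (cl in ord) {
    act <- act + 1L
    vidx <- which(lab == cl)
    co <- arrayInd(vidx, spm@maskDim)
    Fv <- Fvol[vidx]
    # local maxima within the cluster (26-neighbourhood)
    isMax <- vapply(seq_along(vidx), function(i) {
      p <- co[i, ]
      xs <- max(1, p[1] - 1):min(spm@maskDim[1], p[1] + 1)
      ys <- max(1, p[2] - 1):min(spm@maskDim[2], p[2] + 1)
      ts <- max(1, p[3] - 1):min(spm@maskDim[3], p[3] + 1)
      nbv <- Fvol[xs, ys, ts]
      Fv[i] >= max(nbv, na.rm = TRUE)
    }, logical(1))
    cand <- order(Fv, decreasing = TRUE)
    cand <- cand[isMax[cand]]
    sel <- integer()
    for (i in cand) {
      if (length(sel) >= maxPeaks) break
      ok <- TRUE
      for (j in sel) {
        dmm <- sqrt((px[co[i, 1]] - px[co[j, 1]])^2 +
                      (px[co[i, 2]] - px[co[j, 2]])^2)
        dms <- abs(co[i, 3] - co[j, 3]) * dtms
        if (dmm < minPeakSepMm && dms < minPeakSepMs) { ok <- FALSE; break }
      }
      if (ok) sel <- c(sel, i)
    }
    for (i in sel) {
      pF <- Fv[i]
      rows[[length(rows) + 1L]] <- data.frame(
        activation = act, size = sizes[cl],
        latency_ms = spm@times[co[i, 3]],
        p_fwe = if (is.null(resels)) NA_real_ else
          min(1, expectedEC(pF, spm@df, resels)),
        F = pF, Z = fToZ(pF, spm@df))
    }
  }
  do.call(rbind, rows)
}
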
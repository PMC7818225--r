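# Delaunay triangulation (Bowyer-Watson) and barycentric interpolation
# weights for the scalp pixel grid. Ties in the in-circumcircle test are
# treated as inside so that exactly cocircular electrode rings (the outer
# 10% line projects onto a perfect circle) are retriangulated rather than
# dropped; any valid triangulation retains the linear precision that the
# interpolation contract requires.

.circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
              c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12 * max(abs(c(a, b, c)), 1)^2)
    return(c(0, 0, -Inf))                      # collinear: never contains
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
}

.delaunay <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stop("at least 3 electrodes are required for interpolation")
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  R <- max(sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2), 1) * 50
  P <- rbind(pts, c(cx - 2 * R, cy - R), c(cx + 2 * R, cy - R),
             c(cx, cy + 2 * R))
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), nrow = 1)
  cc <- matrix(.circumcircle(P[n + 1, ], P[n + 2, ], P[n + 3, ]), nrow = 1)
  for (i in seq_len(n)) {
    p <- P[i, ]
    d2 <- (p[1] - cc[, 1])^2 + (p[2] - cc[, 2])^2
    bad <- which(d2 <= cc[, 3] * (1 + 1e-9) + 1e-9)
    if (!length(bad)) stop("triangulation failed: degenerate geometry")
    ed <- do.call(rbind, lapply(bad, function(t) {
      v <- tris[t, ]
      rbind(sort(v[1:2]), sort(v[2:3]), sort(v[c(1, 3)]))
    }))
    key <- paste(ed[, 1], ed[, 2])
    boundary <- ed[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    newt <- cbind(boundary, i)
    newc <- t(apply(newt, 1, function(v)
      .circumcircle(P[v[1], ], P[v[2], ], P[v[3], ])))
    tris <- rbind(tris, newt)
    cc <- rbind(cc, newc)
  }
  keep <- rowSums(tris > n) == 0
  out <- tris[keep, , drop = FALSE]
  if (!nrow(out))
    stop("fewer than 3 non-collinear electrodes: cannot triangulate")
  dimnames(out) <- NULL
  out
}

# barycentric coordinates of points (m x 2) in triangle (a, b, c)
.barycentric <- function(pts, a, b, c) {
  det <- (b[2] - c[2]) * (a[1] - c[1]) + (c[1] - b[1]) * (a[2] - c[2])
  l1 <- ((b[2] - c[2]) * (pts[, 1] - c[1]) +
           (c[1] - b[1]) * (pts[, 2] - c[2])) / det
  l2 <- ((c[2] - a[2]) * (pts[, 1] - c[1]) +
           (a[1] - c[1]) * (pts[, 2] - c[2])) / det
  cbind(l1, l2, 1 - l1 - l2)
}

#' Construct a scalp pixel grid
#'
#' Projects the montage onto the plane (see \code{\link{projectElectrodes}}),
#' triangulates the projected electrodes, and precomputes, for every pixel
#' centre inside the interpolation hull, the barycentric weights of its
#' containing triangle. Interpolating a frame then reduces to one
#' matrix-vector product, and the interpolation is exact for affine fields.
#'
#' @param montage a \linkS4class{Montage}.
#' @param n grid side length in pixels.
#' @param pixelSizeMm pixel pitch in mm.
#' @param rimMm planar radius of the projected equator (mm).
#' @param headRadiusMm nominal head radius in mm (used for reporting only).
#' @return A \linkS4class{ScalpGrid}.
#' @examples
#' g <- scalpGrid(makeDefaultMontage())
#' sum(scalpMask(g))
#' @export
scalpGrid <- function(montage, n = 32L, pixelSizeMm = 4.25, rimMm = 60,
                      headRadiusMm = 85) {
  n <- as.integer(n)
  coords <- projectElectrodes(montage, rimMm = rimMm)
  tris <- .delaunay(coords)
  px <- (seq_len(n) - (n + 1) / 2) * pixelSizeMm
  centres <- cbind(rep(px, times = n), rep(px, each = n))  # (i,j) col-major
  npix <- n * n
  W <- matrix(0, npix, nrow(coords))
  assigned <- rep(FALSE, npix)
  for (t in seq_len(nrow(tris))) {
    v <- tris[t, ]
    todo <- which(!assigned)
    if (!length(todo)) break
    lam <- .barycentric(centres[todo, , drop = FALSE],
                        coords[v[1], ], coords[v[2], ], coords[v[3], ])
    inside <- rowSums(lam >= -1e-9) == 3
    hit <- todo[inside]
    if (length(hit)) {
      W[cbind(hit, v[1])] <- lam[inside, 1]
      W[cbind(hit, v[2])] <- lam[inside, 2]
      W[cbind(hit, v[3])] <- lam[inside, 3]
      assigned[hit] <- TRUE
    }
  }
  mask <- matrix(assigned, n, n)
  new("ScalpGrid", n = n, pixelSizeMm = pixelSizeMm, rimMm = rimMm,
      headRadiusMm = headRadiusMm, montage = montage, coords = coords,
      mask = mask, weights = W, triangles = tris)
}

#' Pixel centre coordinates of a grid axis
#'
#' @param grid a \linkS4class{ScalpGrid}.
#' @return numeric vector of pixel-centre positions in mm (shared by both
#'   axes; the grid is square and centred on the vertex).
#' @export
pixelCentres <- function(grid) {
  (seq_len(grid@n) - (grid@n + 1) / 2) * grid@pixelSizeMm
}

#' Interpolate one scalp map frame
#'
#' Barycentric-linear interpolation of per-channel values onto the pixel
#' grid. Pixels outside the electrode hull are NA.
#'
#' @param values numeric vector with one finite value per scalp channel
#'   (montage order, or named by channel).
#' @param grid a \linkS4class{ScalpGrid}.
#' @return numeric n x n matrix in microvolts.
#' @export
interpolateFrame <- function(values, grid) {
  labs <- grid@montage@labels
  if (!is.null(names(values))) values <- values[labs]
  if (length(values) != length(labs) || any(!is.finite(values)))
    stop("one finite value per scalp channel is required")
  img <- matrix(grid@weights %*% values, grid@n, grid@n)
  img[!grid@mask] <- NA_real_
  img
}
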
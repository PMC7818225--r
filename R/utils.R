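# internal numerical helpers

# Butterworth band magnitude at given frequencies (Hz), as the product of a
# high-pass and a low-pass section of `order` poles each (order*6 dB/octave
# per band edge). Returns |H| for single-pass, square it for zero-phase.
.butterMag <- function(fHz, bandHz, fs, order) {
  w <- 2 * pi * fHz / fs
  ejw <- exp(-1i * w)
  hp <- signal::butter(order, 2 * bandHz[1] / fs, type = "high")
  lp <- signal::butter(order, 2 * bandHz[2] / fs, type = "low")
  ev <- function(co) {
    out <- 0 + 0i
    for (c0 in co) out <- out * ejw + c0
    out
  }
  Mod(ev(hp$b) / ev(hp$a)) * Mod(ev(lp$b) / ev(lp$a))
}

.is5smooth <- function(n) {
  for (p in c(2, 3, 5)) while (n %% p == 0) n <- n / p
  n == 1
}

# total padding between lo and hi making n + pad friendly for the FFT
.fftPad <- function(n, lo, hi) {
  for (p in seq(lo, hi)) if (.is5smooth(n + p)) return(p)
  hi
}

# zero-phase band-pass of the columns of a samples x signals matrix:
# frequency-domain application of the squared Butterworth band magnitude
# (the magnitude response of forward-backward filtering), with odd
# reflective padding against edge transients.
.zeroPhaseBandpass <- function(mat, bandHz, fs, order, padSec = 1) {
  nr <- nrow(mat)
  if (bandHz[2] >= fs / 2)
    stop("band upper edge must lie below the Nyquist frequency")
  L <- min(round(padSec * fs), nr - 1L)
  padTot <- if (L > 0) .fftPad(nr, L, 2L * L) else 0L
  L1 <- padTot %/% 2L
  L2 <- padTot - L1
  top <- if (L1 > 0)
    2 * matrix(mat[1L, ], L1, ncol(mat), byrow = TRUE) -
      mat[seq(L1 + 1L, 2L), , drop = FALSE]
  bot <- if (L2 > 0)
    2 * matrix(mat[nr, ], L2, ncol(mat), byrow = TRUE) -
      mat[seq(nr - 1L, nr - L2), , drop = FALSE]
  padded <- rbind(top, mat, bot)
  len <- nrow(padded)
  f <- (seq_len(len) - 1) / len * fs
  f <- pmin(f, fs - f)                       # two-sided spectrum
  mag2 <- .butterMag(f, bandHz, fs, order)^2
  out <- .applyRealSpectrum(padded, mag2)
  out[L1 + seq_len(nr), , drop = FALSE]
}

# multiply the spectrum of every (real) column by a real symmetric gain;
# pairs of columns are packed into one complex FFT (the gain is a real
# linear operator, so real and imaginary parts stay independent)
.applyRealSpectrum <- function(mat, gain) {
  len <- nrow(mat)
  nc <- ncol(mat)
  h <- nc %/% 2L
  out <- matrix(0, len, nc)
  if (h > 0) {
    P <- mat[, seq_len(h), drop = FALSE] +
      1i * mat[, h + seq_len(h), drop = FALSE]
    Fo <- mvfft(mvfft(P) * gain, inverse = TRUE) / len
    out[, seq_len(h)] <- Re(Fo)
    out[, h + seq_len(h)] <- Im(Fo)
  }
  if (nc %% 2L == 1L)
    out[, nc] <- Re(mvfft(mvfft(mat[, nc, drop = FALSE]) * gain,
                          inverse = TRUE)) / len
  out
}

# normalized symmetric Gaussian kernel for a given sigma in sample units
.gaussKernel <- function(sigma) {
  if (sigma < 1e-8) return(1)
  r <- ceiling(4 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# convolve an array along one axis with a symmetric kernel, zero padding
# outside the array (callers divide by the identically convolved mask)
.convAxis <- function(arr, k, axis) {
  if (length(k) == 1L) return(arr)
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- if (axis == 1L) arr else aperm(arr, perm)
  da <- dim(a)
  r <- (length(k) - 1L) %/% 2L
  first <- c(k[(r + 1L):length(k)],
             rep(0, max(0L, da[1] - r - 1L)))[seq_len(da[1])]
  K <- stats::toeplitz(first)
  out <- array(K %*% matrix(a, da[1]), da)
  if (axis == 1L) out else aperm(out, order(perm))
}

# masked (normalized) separable Gaussian smoothing of a 3D array;
# sigmas are in voxel units, mask3 is logical with the same dim
.smoothMasked <- function(values, mask3, sigmas) {
  V <- values
  V[!mask3] <- 0
  M <- array(as.numeric(mask3), dim(mask3))
  for (ax in 1:3) {
    k <- .gaussKernel(sigmas[ax])
    V <- .convAxis(V, k, ax)
    M <- .convAxis(M, k, ax)
  }
  out <- V / M
  out[!mask3] <- NA_real_
  out
}

# linear indices of in-mask voxels for a grid mask replicated over T frames
.maskInfo <- function(mask2, nT) {
  list(dim = c(dim(mask2), nT),
       idx = which(rep(as.vector(mask2), nT)))
}

.voxelsToVolume <- function(x, info) {
  out <- array(NA_real_, info$dim)
  out[info$idx] <- x
  out
}

# deterministic per-subject RNG stream seed (kept below 2^31)
.subseed <- function(seed, subjectId, salt = 0L) {
  as.integer((as.numeric(seed) * 1009 + subjectId * 7919 + salt * 104729) %%
               2147483647)
}
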
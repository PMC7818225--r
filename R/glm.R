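# Single-subject voxelwise GLM: 24 condition means (6 presentations x 4
# blocks) modelled by 4 block indicators plus 4 block-specific mean-centred
# parametric modulators encoding the hypothesized repetition dynamics.
# Model tags: "exponential", "linear", "chdet" (categorical change
# detection). k = 8 regression parameters for every model, so log-model-
# evidence differences reduce to residual sum-of-squares ratios.

.MODELS <- c("exponential", "linear", "chdet")

#' Build a repetition parametric modulator
#'
#' Raw trajectories over presentations 1..n: exponential
#' \code{exp(-(r-1)/tau)}; linear, decreasing with unit steps (so that
#' suppression of a positive component yields a positive beta); change
#' detection, the first-presentation indicator. The returned regressor is
#' the raw trajectory mean-centred to sum zero.
#'
#' @param model one of "exponential", "linear", "chdet".
#' @param nPresentations number of presentations (>= 2).
#' @param tau exponential decay constant (presentation units).
#' @return an object of class "RepetitionRegressor" with elements
#'   \code{model}, \code{raw}, \code{centered}, \code{tau}.
#' @examples
#' buildModulator("chdet")$centered          # 5/6, then -1/6 each
#' buildModulator("linear")$centered         # 2.5 down to -2.5
#' @export
buildModulator <- function(model, nPresentations = 6L, tau = 1) {
  if (nPresentations < 2) stop("at least two presentations are required")
  model <- match.arg(model, .MODELS)
  r <- seq_len(nPresentations)
  raw <- switch(model,
                exponential = exp(-(r - 1) / tau),
                linear = as.numeric(nPresentations - r),
                chdet = as.numeric(r == 1L))
  structure(list(model = model, raw = raw, centered = raw - mean(raw),
                 tau = if (model == "exponential") tau else NA_real_),
            class = "RepetitionRegressor")
}

#' Build a first-level design matrix
#'
#' 24 rows (presentations 1..6 within block 1, then block 2, ...) by 8
#' columns: 4 block indicators followed by 4 block-specific centred
#' modulators. Centring within block makes each modulator orthogonal to
#' its block indicator; the three models share identical indicator columns
#' and differ only in the 4 modulator columns.
#'
#' @param model model tag.
#' @param nBlocks,nPresentations design counts.
#' @param tau exponential decay constant.
#' @return numeric matrix with attributes \code{model} and \code{tau};
#'   full column rank.
#' @export
buildDesign <- function(model, nBlocks = 4L, nPresentations = 6L, tau = 1) {
  mod <- buildModulator(model, nPresentations, tau)
  n <- nBlocks * nPresentations
  X <- matrix(0, n, 2 * nBlocks)
  for (b in seq_len(nBlocks)) {
    rows <- (b - 1) * nPresentations + seq_len(nPresentations)
    X[rows, b] <- 1
    X[rows, nBlocks + b] <- mod$centered
  }
  colnames(X) <- c(paste0("block", seq_len(nBlocks)),
                   paste0("mod_block", seq_len(nBlocks)))
  rownames(X) <- paste0("b", rep(seq_len(nBlocks), each = nPresentations),
                        "p", rep(seq_len(nPresentations), nBlocks))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  attr(X, "model") <- mod$model
  attr(X, "tau") <- mod$tau
  X
}

#' Fit the GLM at every voxel
#'
#' Ordinary least squares of the response matrix on the design, vectorized
#' over voxels via the QR decomposition of X.
#'
#' @param Y numeric matrix, data points x voxels (rows aligned with the
#'   design rows; no NA).
#' @param X design matrix from \code{\link{buildDesign}}.
#' @param subject integer subject id recorded on the fit.
#' @return A \linkS4class{GLMFit} with betas (parameters x voxels), the
#'   per-voxel residual sum of squares, n, k and the model tag.
#' @export
fitGLM <- function(Y, X, subject = NA_integer_) {
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) stop("Y rows must align with design rows")
  if (anyNA(Y)) stop("Y must not contain NA at in-mask voxels")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("design matrix is rank deficient")
  betas <- qr.coef(qrx, Y)
  rss <- colSums((Y - X %*% betas)^2)
  model <- attr(X, "model")
  tau <- attr(X, "tau")
  new("GLMFit", betas = betas, rss = unname(rss), n = nrow(X),
      k = ncol(X), model = if (is.null(model)) "custom" else model,
      tau = if (is.null(tau)) NA_real_ else tau,
      subject = as.integer(subject), design = unclass(X))
}

#' BIC-approximated log model evidence per voxel
#'
#' Under Gaussian residuals the log model evidence is approximated by
#' \code{-(n/2) ln(rss/n) - (k/2) ln(n)} (natural logarithms), a function
#' of the residual sum of squares alone given n and k. Voxels with rss = 0
#' have undefined evidence and are returned as NA (with a warning).
#'
#' @param fit a \linkS4class{GLMFit}.
#' @return numeric vector of log model evidence per voxel.
#' @export
computeLME <- function(fit) {
  rss <- fit@rss
  out <- rep(NA_real_, length(rss))
  ok <- rss > 0
  if (any(!ok))
    warning(sprintf("%d voxels with zero residual: log evidence undefined",
                    sum(!ok)))
  out[ok] <- -(fit@n / 2) * log(rss[ok] / fit@n) -
    (fit@k / 2) * log(fit@n)
  out
}
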
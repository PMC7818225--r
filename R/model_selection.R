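# Voxelwise fixed-effects Bayesian model comparison: per-subject log model
# evidence differences, their sum over subjects (the log group Bayes
# factor), conjunction masks, and summary statistics of the group
# difference maps.

#' Per-subject and group log-model-evidence difference maps
#'
#' @param lmeA,lmeB numeric matrices, subjects x voxels, of per-voxel log
#'   model evidence for the two models (same subjects, same voxels).
#' @param models optional character length-2 model tags for bookkeeping.
#' @return list of class "DeltaLMEMap": \code{perSubject} (S x V),
#'   \code{groupSum} (V; the log group Bayes factor), \code{models}.
#' @export
deltaLME <- function(lmeA, lmeB, models = c("A", "B")) {
  lmeA <- as.matrix(lmeA); lmeB <- as.matrix(lmeB)
  if (!all(dim(lmeA) == dim(lmeB)))
    stop("log-evidence maps must cover the same subjects and voxels")
  d <- lmeA - lmeB
  structure(list(perSubject = d, groupSum = colSums(d), models = models),
            class = "DeltaLMEMap")
}

#' Conjunction of significance masks
#'
#' @param masks list of logical arrays/vectors on the same grid.
#' @param mode "all" (intersection; the default, following the mask used
#'   for constrained comparison) or "any" (union).
#' @return logical array of the common shape.
#' @export
conjunctionMask <- function(masks, mode = c("all", "any")) {
  mode <- match.arg(mode)
  stopifnot(length(masks) >= 1)
  Reduce(if (mode == "all") `&` else `|`, masks)
}

#' Wilcoxon signed-rank test, normal approximation
#'
#' W is the sum of positive signed ranks (average ranks for ties, zeros
#' dropped); Z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 - tie correction),
#' two-tailed normal p, no continuity correction.
#'
#' @param values numeric vector.
#' @return list with \code{W}, \code{Z}, \code{p}, \code{n} (nonzero count).
#' @examples
#' wilcoxonSignedRank(1:10)$Z      # (55 - 27.5) / sqrt(96.25)
#' @export
wilcoxonSignedRank <- function(values) {
  x <- values[values != 0]
  n <- length(x)
  if (n == 0) stop("all values are zero: signed-rank test undefined")
  if (n < 5) warning("fewer than 5 nonzero values: approximation is crude")
  r <- rank(abs(x))
  W <- sum(r[x > 0])
  ties <- table(r)
  tieCorr <- sum(ties^3 - ties) / 48
  v <- n * (n + 1) * (2 * n + 1) / 24 - tieCorr
  Z <- (W - n * (n + 1) / 4) / sqrt(v)
  list(W = W, Z = Z, p = 2 * pnorm(-abs(Z)), n = n)
}

#' One-sample Kolmogorov-Smirnov statistic against the standard normal
#'
#' D = sup |ECDF - Phi| with the asymptotic Kolmogorov p value; the
#' reference is the fixed standard normal (no parameter estimation).
#'
#' @param values numeric vector (n >= 5).
#' @return list with \code{D} and \code{p}.
#' @export
ksStatistic <- function(values) {
  n <- length(values)
  stopifnot(n >= 5)
  x <- sort(values)
  Fx <- pnorm(x)
  D <- max(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n)
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(D = D, p = max(0, min(1, p)))
}

#' Summary row of a group model comparison
#'
#' Median, mean, SD, percentage of voxels with positive group difference,
#' Kolmogorov-Smirnov D and p, Wilcoxon signed-rank Z and p of the group
#' log-evidence differences over a voxel set.
#'
#' @param delta a \code{\link{deltaLME}} map.
#' @param voxelSet logical vector selecting voxels (default: all).
#' @return one-row data.frame with columns comparison, median, mean, std,
#'   pct_positive, ks_D, ks_p, wilcoxon_Z, wilcoxon_p.
#' @export
summarizeComparison <- function(delta, voxelSet = NULL) {
  g <- delta$groupSum
  if (!is.null(voxelSet)) g <- g[as.vector(voxelSet)]
  if (!length(g)) stop("voxel set is empty")
  ks <- ksStatistic(g)
  wx <- wilcoxonSignedRank(g)
  data.frame(comparison = paste(delta$models, collapse = " vs "),
             median = median(g), mean = mean(g), std = sd(g),
             pct_positive = 100 * mean(g > 0),
             ks_D = ks$D, ks_p = ks$p,
             wilcoxon_Z = wx$Z, wilcoxon_p = wx$p)
}

#' Histogram of group evidence differences
#'
#' Bin edges and counts of the group log-evidence differences over a
#' voxel set, in a
#' form directly writable as CSV.
#'
#' @param delta a \code{\link{deltaLME}} map.
#' @param voxelSet optional logical selector.
#' @param nBins number of bins.
#' @return data.frame with columns bin_left, bin_right, count.
#' @export
deltaLMEHistogram <- function(delta, voxelSet = NULL, nBins = 50) {
  g <- delta$groupSum
  if (!is.null(voxelSet)) g <- g[as.vector(voxelSet)]
  h <- hist(g, breaks = nBins, plot = FALSE)
  data.frame(bin_left = h$breaks[-length(h$breaks)],
             bin_right = h$breaks[-1], count = h$counts)
}

#' Interpret a log-evidence difference
#'
#' Conventional evidence labels for |delta|: up to 1, not worth more than
#' a bare mention; 1-3, positive; 3-5, strong; above 5, very strong. The
#' sign determines which model of the ordered pair is favoured.
#'
#' @param delta finite log-evidence difference (model A minus model B).
#' @return list with \code{label} and \code{favours} ("A", "B" or "none").
#' @export
interpretEvidence <- function(delta) {
  stopifnot(is.finite(delta))
  a <- abs(delta)
  label <- if (a > 5) "very strong" else if (a > 3) "strong" else
    if (a > 1) "positive" else if (a > 0) "weak" else "none"
  list(label = label,
       favours = if (delta > 0) "A" else if (delta < 0) "B" else "none")
}
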
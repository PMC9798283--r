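#' Wilcoxon rank-sum z statistic
#'
#' Two-sample rank-sum (Mann-Whitney) test using the normal approximation
#' with tie correction and continuity correction.  The z statistic is signed:
#' positive when \code{x} tends to exceed \code{y}.  Swapping the samples
#' negates z and leaves the two-tail p unchanged.
#'
#' @param x,y numeric samples (non-empty).
#' @param continuity apply the 0.5 continuity correction (default TRUE).
#' @return list with \code{z}, \code{p} (two-tail), and \code{n} (total
#'   observations).
#' @export
ranksumZ <- function(x, y, continuity = TRUE) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(r)
  tieTerm <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
  if (sigma2 <= 0) return(list(z = 0, p = 1, n = N))
  d <- W - mu
  if (continuity) d <- sign(d) * max(0, abs(d) - 0.5)
  z <- d / sqrt(sigma2)
  list(z = z, p = min(1, 2 * pnorm(-abs(z))), n = N)
}

#' Rosenthal effect size
#'
#' The z statistic of a rank test divided by the square root of the total
#' number of observations, \code{z / sqrt(n)}.
#'
#' @param z rank-test z statistic.
#' @param n total number of observations (>= 1).
#' @return signed effect size.
#' @export
rosenthalEffectSize <- function(z, n) {
  if (any(n < 1)) stop("n must be >= 1")
  z / sqrt(n)
}

#' Wilcoxon signed-rank test (paired)
#'
#' Paired two-tail signed-rank test via the normal approximation with tie
#' correction and continuity correction.  Zero differences are dropped before
#' ranking (the standard zero-handling rule); an all-zero difference vector
#' is an error.  The z is signed: positive when \code{x} tends to exceed
#' \code{y}.
#'
#' @param x,y paired samples of equal length >= 2.
#' @return list with \code{z}, \code{p}, \code{n} (non-zero pairs).
#' @export
signedRankTest <- function(x, y) {
  if (length(x) != length(y)) stop("samples must be paired (equal length)")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) stop("all differences are zero")
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(list(z = 0, p = 1, n = n))
  dev <- V - mu
  dev <- sign(dev) * max(0, abs(dev) - 0.5)
  z <- dev / sqrt(sigma2)
  list(z = z, p = min(1, 2 * pnorm(-abs(z))), n = n)
}

#' Kruskal-Wallis test
#'
#' One-way rank analysis of variance over two or more groups (tie-corrected H
#' statistic with a chi-square reference), delegating to
#' \code{stats::kruskal.test}.
#'
#' @param groups list of numeric samples (each non-empty, >= 2 groups).
#' @return list with \code{H}, \code{p}, \code{df}, \code{n}.
#' @export
kruskalTest <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need at least two groups")
  if (any(!lengths(groups))) stop("each group must be non-empty")
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(vals)) == 1)
    return(list(H = 0, p = 1, df = length(groups) - 1, n = length(vals)))
  kt <- stats::kruskal.test(vals, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), n = length(vals))
}

#' Bonferroni correction
#'
#' Elementwise \code{min(1, p * m)} for a stated number of comparisons
#' \code{m} (which may exceed the number of p-values supplied).
#'
#' @param p numeric p-values.
#' @param m number of comparisons (default: \code{length(p)}).
#' @return adjusted p-values.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  if (m < length(p)) stop("m must be >= number of p-values")
  pmin(1, p * m)
}

.fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

.gaussKernel1D <- function(fwhm) {
  sigma <- .fwhmToSigma(fwhm)
  radius <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable 1D convolution along matrix rows with reflect boundary
.convRowsReflect <- function(m, k) {
  radius <- (length(k) - 1) / 2
  n <- nrow(m)
  idx <- c(rev(seq_len(min(radius, n))), seq_len(n),
           n + 1 - rev(seq_len(min(radius, n))))
  while (length(idx) < n + 2 * radius) idx <- c(idx[1], idx, idx[length(idx)])
  padded <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * padded[(j):(j + n - 1), , drop = FALSE]
  out
}

#' 2D Gaussian smoothing
#'
#' Convolution of a grid map with a normalised, separable 2D Gaussian kernel
#' (full width at half maximum in grid units), reflect boundary.  A constant
#' map is preserved exactly.
#'
#' @param map numeric matrix.
#' @param fwhm kernel full width at half maximum in grid units (> 0).
#' @return smoothed matrix of the same shape.
#' @export
gaussianSmooth2D <- function(map, fwhm) {
  if (!is.matrix(map)) stop("map must be a matrix")
  if (!is.finite(fwhm) || fwhm <= 0) stop("fwhm must be positive")
  k <- .gaussKernel1D(fwhm)
  out <- .convRowsReflect(map, k)
  t(.convRowsReflect(t(out), k))
}

# zero-padded separable convolution (no normalisation)
.convRowsZero <- function(m, k) {
  radius <- (length(k) - 1) / 2
  n <- nrow(m)
  padded <- rbind(matrix(0, radius, ncol(m)), m, matrix(0, radius, ncol(m)))
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * padded[(j):(j + n - 1), , drop = FALSE]
  out
}

.convZero2D <- function(m, k) {
  t(.convRowsZero(t(.convRowsZero(m, k)), k))
}

# Mask-renormalised Gaussian smoothing with exact per-pixel variance
# standardisation: smoothing weights are the truncated kernel renormalised to
# sum 1 inside the grid, and the smoothed map is divided by the standard
# deviation it would have under i.i.d. unit-variance input, making the
# smoothed null field unit-variance at every pixel (including edges).
.smoothStandardise <- function(map, fwhm) {
  k <- .gaussKernel1D(fwhm)
  ones <- matrix(1, nrow(map), ncol(map))
  num <- .convZero2D(map, k)
  den <- .convZero2D(ones, k)
  sumSq <- .convZero2D(ones, k^2)
  smoothed <- num / den
  stddev <- sqrt(sumSq) / den
  list(smoothed = smoothed, standardised = smoothed / stddev)
}

# expected Euler characteristic of excursions of a unit-variance smooth 2D
# Gaussian field above u, for a rectangular search region of nx x ny pixels
# with smoothness FWHM (in pixels): EC densities of dimension 0..2 times the
# resel counts of the rectangle.
.expectedEC <- function(u, nx, ny, fwhm) {
  r2 <- (nx - 1) * (ny - 1) / fwhm^2
  r1 <- ((nx - 1) + (ny - 1)) / fwhm
  r0 <- 1
  rho0 <- pnorm(u, lower.tail = FALSE)
  rho1 <- sqrt(4 * log(2)) / (2 * pi) * exp(-u^2 / 2)
  rho2 <- 4 * log(2) / (2 * pi)^1.5 * u * exp(-u^2 / 2)
  r0 * rho0 + r1 * rho1 + r2 * rho2
}

#' Random-field family-wise z threshold
#'
#' Returns the cutoff u such that the expected number of suprathreshold
#' clusters of a smooth unit-variance 2D Gaussian null field of the map's
#' size and smoothness equals alpha (expected-Euler-characteristic
#' approximation).  With \code{twoTailed} (the default) the excursions of
#' both signs are counted, i.e. the threshold solves 2 E[EC(u)] = alpha.
#' The threshold is monotone decreasing in alpha and approaches the pointwise
#' two-tail Gaussian quantile as the smoothness grows beyond the map size.
#'
#' @param map numeric matrix (only its size is used), or an integer c(nx, ny).
#' @param fwhm field smoothness FWHM in grid units.
#' @param alpha family-wise level in (0, 1).
#' @param twoTailed count excursions of both signs (default TRUE).
#' @return the z threshold.
#' @export
rftThreshold <- function(map, fwhm, alpha = 0.05, twoTailed = TRUE) {
  dims <- if (is.matrix(map)) dim(map) else as.integer(map)
  if (length(dims) != 2 || any(dims < 2)) stop("degenerate map size")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (!is.finite(fwhm) || fwhm <= 0) stop("fwhm must be positive")
  tails <- if (twoTailed) 2 else 1
  f <- function(u) tails * .expectedEC(u, dims[1], dims[2], fwhm) - alpha
  if (f(0.5) < 0) return(uniroot(f, c(1e-6, 0.5))$root)
  uniroot(f, c(0.5, 20))$root
}

#' Chi-square goodness-of-fit test of normality
#'
#' Bins the sample into deciles of a normal distribution fitted by the sample
#' moments (equiprobable bins) and compares observed and expected counts with
#' a chi-square statistic on bins - 3 degrees of freedom.
#'
#' @param x numeric sample, n >= 20.
#' @param bins number of equiprobable bins (default 10).
#' @return list with \code{statistic}, \code{p}, \code{df}, \code{n}.
#' @export
chisqNormalityTest <- function(x, bins = 10) {
  n <- length(x)
  if (n < 20) stop("need at least 20 observations")
  s <- sd(x)
  if (s == 0) stop("zero variance sample")
  breaks <- qnorm(seq(0, 1, length.out = bins + 1), mean(x), s)
  breaks[1] <- -Inf; breaks[bins + 1] <- Inf
  obs <- table(cut(x, breaks))
  expd <- n / bins
  stat <- sum((as.numeric(obs) - expd)^2 / expd)
  df <- bins - 3
  list(statistic = stat, p = pchisq(stat, df, lower.tail = FALSE),
       df = df, n = n)
}
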
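#' Frequency band definitions
#'
#' The four filtering conditions applied to BOLD signals: no filtering
#' (\code{NF}), broad band \code{BF} = (0.01, 0.1) Hz, low band \code{LF} =
#' (0.01, 0.05) Hz and high band \code{HF} = (0.05, 0.1) Hz.
#'
#' @param band band name.
#' @return for \code{bandLimits}: numeric c(low, high) in Hz, or NULL for NF.
#' @export
bandLimits <- function(band) {
  switch(match.arg(band, .BANDS),
         NF = NULL,
         BF = c(0.01, 0.1),
         LF = c(0.01, 0.05),
         HF = c(0.05, 0.1))
}

#' @rdname bandLimits
#' @export
bandNames <- function() .BANDS

# odd (point-reflected) padding used ahead of the zero-phase filter, so that
# edge transients fall on the padding, not the data
.reflectPad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  c(left, x, right)
}

#' Band-pass filter BOLD signals
#'
#' Applies an order-6 Butterworth band-pass per region, forward and backward
#' (zero phase), with odd-reflection edge padding of at least three filter
#' lengths.  Band \code{NF} returns the input unchanged.  Both cutoffs must
#' lie below the Nyquist frequency 1/(2 TR).
#'
#' @param ts a \linkS4class{BoldTimeSeries}.
#' @param band target band name.
#' @param order filter order (default 6).
#' @return a filtered \linkS4class{BoldTimeSeries} tagged with \code{band}.
#' @export
bandpassFilter <- function(ts, band, order = 6) {
  stopifnot(is(ts, "BoldTimeSeries"))
  band <- match.arg(band, .BANDS)
  lim <- bandLimits(band)
  if (is.null(lim)) {
    ts@band <- "NF"
    return(ts)
  }
  fs <- 1 / ts@tr
  nyq <- fs / 2
  if (any(lim >= nyq))
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 max(lim), nyq))
  bf <- signal::butter(order, lim / nyq, type = "pass")
  flen <- max(length(bf$b), length(bf$a))
  # generous padding: the slow band edges ring over ~1/(low tr) samples
  pad <- max(3 * flen, 10 * ceiling(1 / (lim[1] * ts@tr)))
  x <- ts@values
  out <- t(apply(x, 1, function(row) {
    padded <- .reflectPad(row, pad)
    padActual <- (length(padded) - length(row)) / 2
    fwd <- as.numeric(signal::filter(bf, padded))
    bwd <- rev(as.numeric(signal::filter(bf, rev(fwd))))
    bwd[(padActual + 1):(padActual + length(row))]
  }))
  new("BoldTimeSeries", values = out, tr = ts@tr, band = band)
}

#' Theoretical zero-phase Butterworth band gain
#'
#' Squared magnitude response of the digitally designed order-n Butterworth
#' band-pass applied forward and backward, evaluated through the bilinear
#' frequency mapping (the digital response at frequency f equals the analog
#' prototype at 2 fs tan(pi f / fs), with band edges prewarped the same way).
#'
#' @param f frequency in Hz (vectorised).
#' @param band band name (BF, LF or HF).
#' @param tr sampling interval in seconds.
#' @param order filter order (default 6).
#' @return gain of the zero-phase (two-pass) filter at \code{f}.
#' @export
butterworthBandGain <- function(f, band, tr, order = 6) {
  lim <- bandLimits(band)
  if (is.null(lim)) return(rep(1, length(f)))
  fs <- 1 / tr
  warp <- function(fr) 2 * fs * tan(pi * fr / fs)
  W1 <- warp(lim[1]); W2 <- warp(lim[2]); W <- warp(f)
  ratio <- (W^2 - W1 * W2) / (W * (W2 - W1))
  onePass <- 1 / (1 + ratio^(2 * order))
  onePass  # |H|^2: the two-pass (zero-phase) power gain on amplitudes
}

#' Pearson functional connectivity
#'
#' Pairwise Pearson correlation between the regional time series of a BOLD
#' matrix.  Regions with zero variance abort with an error naming the region.
#'
#' @param ts a \linkS4class{BoldTimeSeries}.
#' @param source provenance tag, \code{"empirical"} or \code{"simulated"}.
#' @return a \linkS4class{FunctionalConnectome}.
#' @export
pearsonFC <- function(ts, source = c("empirical", "simulated")) {
  stopifnot(is(ts, "BoldTimeSeries"))
  source <- match.arg(source)
  x <- ts@values
  if (ncol(x) < 3) stop("need at least 3 time points")
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop(sprintf("zero-variance region(s): %s", paste(bad, collapse = ", ")))
  }
  m <- cor(t(x))
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- NULL
  new("FunctionalConnectome", values = m, band = ts@band, source = source)
}

#' Correlation between two connectomes
#'
#' Pearson correlation between the strict upper triangles (self-connections
#' excluded) of two square matrices of the same size; this is the
#' goodness-of-fit scalar used throughout model validation, and the
#' structure-function relationship corr(eFC, eSC).
#'
#' @param a,b square numeric matrices (or \linkS4class{FunctionalConnectome}/
#'   \linkS4class{StructuralConnectome} objects; SC enters as raw counts).
#' @return Pearson correlation in [-1, 1].
#' @export
connectomeRelationship <- function(a, b) {
  a <- .asSquareMatrix(a)
  b <- .asSquareMatrix(b)
  if (!identical(dim(a), dim(b))) stop("matrices must have the same shape")
  if (nrow(a) < 3) stop("need at least 3 regions")
  ua <- a[upper.tri(a)]
  ub <- b[upper.tri(b)]
  if (sd(ua) == 0 || sd(ub) == 0)
    stop("zero variance in an upper triangle; correlation undefined")
  cor(ua, ub)
}

.asSquareMatrix <- function(x) {
  if (is(x, "FunctionalConnectome")) return(x@values)
  if (is(x, "StructuralConnectome")) return(x@sc)
  if (!is.matrix(x) || nrow(x) != ncol(x)) stop("expected a square matrix")
  x
}
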
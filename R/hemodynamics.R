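#' Balloon-Windkessel parameters
#'
#' Constructor for \linkS4class{BWParams}; defaults are the standard 3 T
#' values (see the class documentation).
#'
#' @param TE echo time, s.
#' @param tMTT mean transit time, s.
#' @param E0 resting oxygen extraction fraction.
#' @param V0 resting venous volume fraction.
#' @param theta0 frequency offset, 1/s.
#' @param epsilon intra/extra-vascular signal ratio.
#' @param r0 sensitivity slope, 1/s.
#' @param alpha flow-volume exponent.
#' @param kappa,gamma rate constants, Hz.
#' @return a \linkS4class{BWParams} object.
#' @export
bwParams <- function(TE = 0.030, tMTT = 2, E0 = 0.4, V0 = 0.04, theta0 = 80.6,
                     epsilon = 0.3, r0 = 25, alpha = 0.38, kappa = 0.64,
                     gamma = 0.32) {
  new("BWParams", TE = TE, tMTT = tMTT, E0 = E0, V0 = V0, theta0 = theta0,
      epsilon = epsilon, r0 = r0, alpha = alpha, kappa = kappa, gamma = gamma)
}

#' BOLD observation equation
#'
#' Maps a hemodynamic state (venous volume \code{v}, deoxyhemoglobin
#' \code{q}) to the BOLD signal:
#' \code{V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))} with
#' \code{k1 = 4.3 theta0 E0 TE}, \code{k2 = epsilon r0 E0 TE},
#' \code{k3 = 1 - epsilon}.
#'
#' @param v venous volume (normalised, > 0).
#' @param q deoxyhemoglobin content (normalised, > 0).
#' @param params a \linkS4class{BWParams}.
#' @return BOLD signal value(s).
#' @export
boldObservation <- function(v, q, params = bwParams()) {
  if (any(v <= 0) || any(q <= 0)) stop("v and q must be positive")
  k1 <- 4.3 * params@theta0 * params@E0 * params@TE
  k2 <- params@epsilon * params@r0 * params@E0 * params@TE
  k3 <- 1 - params@epsilon
  params@V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
}

#' Convert neural activity to BOLD via the Balloon-Windkessel model
#'
#' Integrates, per region, the hemodynamic system (vasodilatory signal s,
#' inflow f, venous volume v, deoxyhemoglobin q) from the resting state
#' [0, 1, 1, 1] with fixed-step RK4 at the neural time step, driven by the
#' supplied neural input.  The BOLD observation is sampled once per TR.  A
#' non-positive balloon state raises an error naming the failing step rather
#' than being clipped.
#'
#' @param neuralInput regions x samples matrix at step \code{dt} (a vector is
#'   treated as one region).  Column k is the input at time (k-1) dt.
#' @param dt input time step in seconds.
#' @param tr output sampling interval in seconds (must be >= dt; each output
#'   sample is taken at the integration step nearest k tr).
#' @param params a \linkS4class{BWParams}.
#' @param returnStates logical; additionally return the full [s, f, v, q]
#'   trajectories (4 rows per region) for diagnostics.
#' @return regions x floor(T/tr) BOLD matrix (sampled at the end of each TR),
#'   or a list with \code{bold} and \code{states} if \code{returnStates}.
#' @export
bwBold <- function(neuralInput, dt, tr = dt, params = bwParams(),
                   returnStates = FALSE) {
  if (is.vector(neuralInput)) neuralInput <- matrix(neuralInput, nrow = 1)
  if (dt <= 0) stop("dt must be positive")
  if (tr < dt) stop("tr must be >= dt")
  out <- .bw_integrate_cpp(neuralInput, dt, params@TE, params@tMTT, params@E0,
                           params@V0, params@theta0, params@epsilon,
                           params@r0, params@alpha, params@kappa,
                           params@gamma, tr, returnStates)
  if (returnStates) out else out$bold
}

#' Simulated BOLD from the forward model
#'
#' Full forward model for one subject: neural-mass network simulation on the
#' structural connectome, per-region standardisation (z-scoring over the
#' post-transient window) of the EPSP as the dimensionless hemodynamic drive,
#' Balloon-Windkessel conversion, and sampling at the repetition time.
#'
#' @param connectome a \linkS4class{StructuralConnectome}.
#' @param C global coupling.
#' @param tauGlobal global delay, s/m.
#' @param duration post-transient simulated time, s.
#' @param tr repetition time, s.
#' @param dt integration step, s.
#' @param seed integer seed.
#' @param nmParams neural-mass parameters.
#' @param bwPar hemodynamic parameters.
#' @param transient discarded initial time, s.
#' @param gain scaling applied to the standardised EPSP drive (default 0.05,
#'   keeping the balloon states well inside their positive domain even for
#'   strongly oscillatory network regimes).
#' @param couplingScaledByN see \code{\link{simulateNetwork}}.
#' @param bwDt hemodynamic integration step, s (default 25 ms; the balloon
#'   time constants are of order seconds).  The standardised drive is
#'   block-averaged (anti-aliased) from the neural step to this step before
#'   the RK4 integration; rounded to an integer multiple of \code{dt}.
#' @return a \linkS4class{BoldTimeSeries} (band \code{NF}) with
#'   floor(duration/tr) samples per region.
#' @export
simulateBold <- function(connectome, C, tauGlobal, duration, tr,
                         dt = 1e-3, seed = 1,
                         nmParams = neuralMassParams(), bwPar = bwParams(),
                         transient = 20, gain = 0.05,
                         couplingScaledByN = TRUE, bwDt = 0.025) {
  sim <- simulateNetwork(connectome, nmParams, C = C, tauGlobal = tauGlobal,
                         duration = duration, dt = dt, seed = seed,
                         transient = transient,
                         couplingScaledByN = couplingScaledByN)
  ye <- sim$ye
  nT <- ncol(ye)
  mu <- rowMeans(ye)
  sdv <- sqrt(pmax(rowSums(ye * ye) / nT - mu^2, 0) * nT / (nT - 1))
  if (any(sdv == 0)) stop("constant EPSP signal; cannot standardise drive")
  x <- (ye - mu) / sdv * gain
  stride <- max(1L, as.integer(round(bwDt / dt)))
  if (stride > 1L) {
    nBlock <- (ncol(x) - 1L) %/% stride
    body <- x[, 1L + seq_len(nBlock * stride), drop = FALSE]
    dim(body) <- c(nrow(x) * stride, nBlock)
    blockMeans <- rowsum(body, rep(seq_len(nrow(x)), stride)) / stride
    x <- cbind(x[, 1L], blockMeans)
  }
  bold <- bwBold(x, dt = stride * dt, tr = tr, params = bwPar)
  new("BoldTimeSeries", values = bold, tr = tr, band = "NF")
}
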
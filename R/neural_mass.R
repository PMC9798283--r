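#' Neural-mass model parameters
#'
#' Constructor for \linkS4class{NeuralMassParams}.  Units: \code{Fe},
#' \code{Fi}, \code{a}, \code{b} in 1/s; \code{A}, \code{B}, \code{v0} in mV;
#' \code{r} in 1/mV; \code{R}, \code{Cie}, \code{Cei} dimensionless;
#' \code{noiseAmplitude} in V/s^2 (bound of the uniform forcing).
#'
#' @param Fe,Fi maximal excitatory/inhibitory firing densities.
#' @param a,b reciprocal EPSP/IPSP kernel time constants.
#' @param A,B maximal EPSP/IPSP kernel amplitudes.
#' @param r sigmoid slope.
#' @param v0 half-activation potential.
#' @param Cie,Cei intra-regional couplings (excitatory to inhibitory and back).
#' @param R frequency scaling factor.
#' @param noiseAmplitude bound of the uniform noise on the current derivatives.
#' @return a \linkS4class{NeuralMassParams} object.
#' @export
neuralMassParams <- function(Fe = 100, Fi = 50, a = 100, b = 50, A = 3.25,
                             B = 22, r = 0.56, v0 = 6, Cie = 6, Cei = 6,
                             R = 2.2, noiseAmplitude = 1.5) {
  new("NeuralMassParams", Fe = Fe, Fi = Fi, a = a, b = b, A = A, B = B,
      r = r, v0 = v0, Cie = Cie, Cei = Cei, R = R,
      noiseAmplitude = noiseAmplitude)
}

#' Population sigmoid functions
#'
#' Convert a membrane potential (mV) to an average firing density (1/s):
#' \code{Fmax / (1 + exp(r (v0 - v)))}.  \code{sigmoidE} uses the excitatory
#' maximum \code{Fe}, \code{sigmoidI} the inhibitory maximum \code{Fi}.
#'
#' @param v potential in mV (vectorised).
#' @param params a \linkS4class{NeuralMassParams} object.
#' @return firing density in 1/s, strictly increasing in \code{v} and bounded
#'   in (0, Fmax).
#' @export
sigmoidE <- function(v, params = neuralMassParams()) {
  params@Fe / (1 + exp(params@r * (params@v0 - v)))
}

#' @rdname sigmoidE
#' @export
sigmoidI <- function(v, params = neuralMassParams()) {
  params@Fi / (1 + exp(params@r * (params@v0 - v)))
}

#' Normalised coupling weights from streamline counts
#'
#' The inter-regional coupling weight from region m to region n is the
#' streamline count w_nm divided by the average count W over all off-diagonal
#' connections (self-connections excluded).  An all-equal count matrix thus
#' yields unit weights everywhere.
#'
#' @param connectome a \linkS4class{StructuralConnectome}.
#' @return list with \code{cnm} (weight matrix, zero diagonal) and \code{W}
#'   (the average streamline count).
#' @export
couplingFromSC <- function(connectome) {
  sc <- scMatrix(connectome)
  off <- !diag(nrow(sc))
  W <- mean(sc[off])
  if (W <= 0) stop("empty connectome: average streamline count is zero")
  cnm <- sc / W
  diag(cnm) <- 0
  list(cnm = cnm, W = W)
}

#' Pairwise delays from path lengths
#'
#' Scales the average path lengths (mm) by the global delay parameter (s/m):
#' \code{tau_nm = tauGlobal * L_nm / 1000}.  Entries are zero where the path
#' length is zero (absent connections).
#'
#' @param pl path-length matrix in mm.
#' @param tauGlobal global delay in s/m (non-negative).
#' @return delay matrix in seconds.
#' @export
delaysFromPL <- function(pl, tauGlobal) {
  if (length(tauGlobal) != 1 || !is.finite(tauGlobal) || tauGlobal < 0)
    stop("tauGlobal must be a non-negative scalar")
  tauGlobal * pl / 1000
}

#' Biologically feasible global-delay band (s/m)
#'
#' Range of the global delay parameter consistent with electrophysiological
#' conduction speeds, used to flag optima in reports.
#' @export
feasibleDelayRange <- function() c(0.06, 0.25)

#' Simulate the delay-coupled neural-mass network
#'
#' Integrates the two-population model on a structural connectome with
#' fixed-step Euler at step \code{dt}.  Inter-regional coupling acts between
#' the excitatory populations: region n receives the delayed EPSPs of the
#' other regions, weighted by the normalised streamline counts and (by
#' default) scaled by \code{C/N}.  Delays are the path lengths scaled by
#' \code{tauGlobal} and rounded to the nearest integer multiple of \code{dt};
#' the delay history before t = 0 holds the (zero) initial state.  Bounded
#' uniform noise is redrawn per population, region and step.  The first
#' \code{transient} seconds are discarded.
#'
#' @param connectome a \linkS4class{StructuralConnectome}.
#' @param params a \linkS4class{NeuralMassParams}.
#' @param C global coupling (dimensionless, >= 0).
#' @param tauGlobal global delay in s/m.
#' @param duration post-transient simulated time in seconds.
#' @param dt integration step in seconds (default 1 ms).
#' @param seed integer seed; runs are bit-identical given the seed.
#' @param transient discarded initial time in seconds (default 20).
#' @param couplingScaledByN logical; divide the delayed coupling sum by the
#'   number of regions (default TRUE).
#' @param keepYi logical; also return the IPSP series.
#' @return list with \code{ye} (regions x samples EPSP matrix including the
#'   sample at the transient boundary), optionally \code{yi}, and \code{dt}.
#' @export
simulateNetwork <- function(connectome, params = neuralMassParams(), C = 0,
                            tauGlobal = 0, duration = 60, dt = 1e-3,
                            seed = 1, transient = 20,
                            couplingScaledByN = TRUE, keepYi = FALSE) {
  stopifnot(is(connectome, "StructuralConnectome"))
  if (dt <= 0) stop("dt must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (C < 0) stop("C must be non-negative")
  if (dt > 0.5 / (params@a * params@R))
    stop(sprintf("dt = %g s too large for the kernel rate 1/(aR) = %g s",
                 dt, 1 / (params@a * params@R)))
  cw <- couplingFromSC(connectome)
  tau <- delaysFromPL(plMatrix(connectome), tauGlobal)
  delaySteps <- matrix(as.integer(round(tau / dt)), nrow = nrow(tau))
  nSteps <- as.integer(round(duration / dt))
  nTransient <- as.integer(round(transient / dt))
  set.seed(as.integer(seed))
  # the model equations are written in mV; the noise bound is stated in V/s^2
  out <- .nm_simulate_cpp(cw$cnm, delaySteps, C, couplingScaledByN,
                          params@Fe, params@Fi, params@a, params@b,
                          params@A, params@B, params@r, params@v0,
                          params@Cie, params@Cei, params@R,
                          params@noiseAmplitude * 1000, dt, nSteps,
                          nTransient, keepYi)
  out$dt <- dt
  out
}

#' Welch-averaged power spectral density
#'
#' Averaged periodogram over 50%-overlapping Hann-windowed segments.  The
#' window power is compensated so that the integral of the PSD approximates
#' the signal variance (Parseval consistency).
#'
#' @param x numeric vector, at least 64 samples.
#' @param dt sampling interval in seconds.
#' @param nSegment segment length (default: largest power of two giving at
#'   least 4 segments, capped at 4096).
#' @return data.frame with columns \code{freq} (Hz) and \code{power}.
#' @export
welchPSD <- function(x, dt, nSegment = NULL) {
  n <- length(x)
  if (n < 64) stop("need at least 64 samples")
  if (is.null(nSegment))
    nSegment <- min(4096, 2^floor(log2(n / 4)))
  nSegment <- max(16, min(nSegment, n))
  step <- max(1, floor(nSegment / 2))
  starts <- seq(1, n - nSegment + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nSegment) / (nSegment + 1))
  wNorm <- sum(w^2)
  nf <- floor(nSegment / 2)
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nSegment - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg))^2
    acc <- acc + sp[2:(nf + 1)]
  }
  power <- acc / length(starts) * dt / wNorm * 2
  freq <- (1:nf) / (nSegment * dt)
  data.frame(freq = freq, power = power)
}

#' Spectral peak frequency
#'
#' Frequency of the maximal Welch PSD value above a minimum frequency.
#'
#' @param x numeric vector.
#' @param dt sampling interval in seconds.
#' @param fMin ignore bins below this frequency (Hz).
#' @return peak frequency in Hz.
#' @export
spectralPeak <- function(x, dt, fMin = 0.5) {
  psd <- welchPSD(x, dt)
  keep <- psd$freq >= fMin
  psd$freq[keep][which.max(psd$power[keep])]
}

#' Algebraic fixed point of the uncoupled deterministic node
#'
#' For zero global coupling and zero noise each region settles to the unique
#' solution of \code{y_e = (A/a) sigmoidE(-Cei y_i)},
#' \code{y_i = (B/b) sigmoidI(Cie y_e)} (the frequency scaling factor cancels
#' at rest).  Solved by damped fixed-point iteration to machine precision;
#' used as a reference for integrator checks.
#'
#' @param params a \linkS4class{NeuralMassParams}.
#' @param tol convergence tolerance.
#' @return list with \code{ye} and \code{yi} (mV).
#' @export
nodeFixedPoint <- function(params = neuralMassParams(), tol = 1e-12) {
  ye <- 0
  for (k in 1:10000) {
    yi <- params@B / params@b * sigmoidI(params@Cie * ye, params)
    yeNew <- params@A / params@a * sigmoidE(-params@Cei * yi, params)
    if (abs(yeNew - ye) < tol) {
      ye <- yeNew
      break
    }
    ye <- 0.5 * (ye + yeNew)
  }
  yi <- params@B / params@b * sigmoidI(params@Cie * ye, params)
  list(ye = ye, yi = yi)
}
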
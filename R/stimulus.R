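#' Construct an equal-amplitude random-phase multisine ("white noise")
#' current
#'
#' Sum of sinusoids with one component per requested frequency, equal
#' amplitudes and phases drawn uniformly on `[0, 2 pi)` from `seed`:
#' `x(t) = sum_k amplitude * cos(2 pi f_k t + phase_k)`. The amplitude
#' spectrum extracted from the series ([extractSpectrum()]) is flat at
#' `amplitude` over the component frequencies; the same seed always
#' reproduces the same series.
#'
#' @param frequencies component frequencies, Hz.
#' @param amplitude amplitude per component, nA.
#' @param seed integer phase seed.
#' @param duration record length, ms (must cover at least one period of the
#'   lowest nonzero frequency; choose an integer number of periods of every
#'   component for leakage-free analysis).
#' @param dt sampling interval, ms (must resolve the highest frequency).
#' @return list with `time` (ms), `current` (nA), and `spec`
#'   (the corresponding [StimulusSpec-class]).
#' @export
makeMultisine <- function(frequencies, amplitude = 1, seed = 1L,
                          duration = 1000, dt = 0.05) {
  fmax <- max(frequencies)
  if (dt >= 500 / fmax)
    stop("value error: dt too coarse for the highest frequency (Nyquist)")
  fmin <- min(frequencies[frequencies > 0])
  if (is.finite(fmin) && duration < 1000 / fmin)
    stop("duration must cover at least one period of the lowest frequency")
  spec <- multisineStimulus(frequencies, amplitude, seed)
  tms <- seq(0, duration - dt, by = dt)
  x <- rep(0, length(tms))
  for (k in seq_along(frequencies)) {
    x <- x + amplitude * cos(2 * pi * frequencies[k] * tms / 1000 +
                             spec@phases[k])
  }
  list(time = tms, current = x, spec = spec)
}

#' Brute-force time-domain integration of the passive cable system
#'
#' Independent oracle for the frequency-domain solver: integrates
#' `C dv/dt = -(Gm + L) v + i(t) e_site` with an implicit theta scheme
#' (default `theta = 0.5`, trapezoidal). The stimulus is inward-positive as
#' in [solveIntracellular()]; after the transient has settled
#' (about `5 tau_m`) the steady-state sinusoidal amplitude matches the
#' frequency-domain solve.
#'
#' @param morph a [Morphology-class].
#' @param mem a [PassiveMembrane-class].
#' @param stimulus stimulus current samples, nA.
#' @param site injected compartment index.
#' @param dt time step, ms. Guarded against instability/accuracy loss:
#'   must resolve the membrane time constant (`dt < tau_m / 20`).
#' @param theta implicitness parameter in (0, 1]; 0.5 = trapezoidal,
#'   1 = backward Euler.
#' @return matrix of membrane-potential deviations, compartments x time, mV.
#' @export
simulateTimeDomain <- function(morph, mem, stimulus, site, dt,
                               theta = 0.5) {
  n <- nCompartments(morph)
  if (site < 1L || site > n) stop("site out of range")
  if (theta <= 0 || theta > 1) stop("theta must be in (0, 1]")
  tb <- .membrane_tables(morph, mem)
  taus <- tb$c / tb$g                  # per-compartment membrane tau, ms
  if (dt >= min(taus) / 20)
    stop("instability guard: dt must be < tau_m / 20 (",
         format(min(taus) / 20), " ms)")
  G <- .axial_laplacian(morph, mem) + diag(tb$g, nrow = n)
  Cdt <- diag(tb$c / dt, nrow = n)
  M1inv <- solve(Cdt + theta * G)
  M2 <- Cdt - (1 - theta) * G
  nt <- length(stimulus)
  out <- matrix(0, n, nt)
  v <- rep(0, n)
  e <- rep(0, n); e[site] <- 1
  for (k in 2:nt) {
    rhs <- M2 %*% v + (theta * stimulus[k] + (1 - theta) * stimulus[k - 1]) * e
    v <- as.numeric(M1inv %*% rhs)
    out[, k] <- v
  }
  out
}
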
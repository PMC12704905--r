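#' Extracellular potential of a point current source
#'
#' `Ve = I / (4 pi sigma r)` in an infinite homogeneous medium. In the
#' package's unit system (nA, um, S/m) the result is in mV with no extra
#' numerical factor.
#'
#' @param I current, nA (numeric or complex; may be a vector per frequency).
#' @param source 3-vector source position, um.
#' @param obs 3-vector observation position, um.
#' @param sigma extracellular conductivity, S/m.
#' @return Ve, mV (same length as `I`).
#' @export
vePointSource <- function(I, source, obs, sigma = 0.3) {
  r <- sqrt(sum((obs - source)^2))
  if (r < 1e-9) stop("singularity: observation point coincides with source")
  I / (4 * pi * sigma * r)
}

#' Point-source kernel between a point and all compartment midpoints
#'
#' `K_n = 1 / (4 pi sigma |r - r_n|)` in mV/nA, with distances clamped from
#' below at each compartment's radius to avoid the 1/r singularity. The same
#' kernel is used for mapping membrane currents to extracellular potentials
#' and for mapping an extracellular stimulation current to the potentials it
#' imposes at the compartments, which keeps the two directions of the
#' reciprocity relation numerically identical.
#'
#' @param morph a [Morphology-class].
#' @param point 3-vector, um.
#' @param sigma conductivity, S/m.
#' @return numeric vector, one entry per compartment, mV/nA.
#' @export
pointSourceKernel <- function(morph, point, sigma = 0.3) {
  mid <- midpoints(morph)
  r <- sqrt((mid[, 1] - point[1])^2 + (mid[, 2] - point[2])^2 +
            (mid[, 3] - point[3])^2)
  r <- pmax(r, morph@compartments$diameter / 2)
  1 / (4 * pi * sigma * r)
}

#' Extracellular potential generated by a cable solution
#'
#' Point-source sum over compartments:
#' `Ve(r, f) = sum_n im_n(f) / (4 pi sigma |r - r_n|)` with compartment
#' midpoints as source locations. Observation points closer to a midpoint
#' than that compartment's radius are clamped to the radius.
#'
#' @param sol a [CableSolution-class].
#' @param morph the [Morphology-class] the solution was computed on.
#' @param obs matrix of observation points (rows) or a single 3-vector, um.
#' @param sigma conductivity, S/m.
#' @return complex matrix, observation points x frequencies, mV.
#' @export
veFromSolution <- function(sol, morph, obs, sigma = 0.3) {
  if (is.vector(obs)) obs <- matrix(obs, ncol = 3L)
  K <- t(apply(obs, 1L, function(p) pointSourceKernel(morph, p, sigma)))
  if (nCompartments(morph) == 1L) K <- matrix(K, ncol = 1L)
  K %*% sol@im
}

#' Near-field monopole approximation
#'
#' Close to the injected compartment the extracellular potential is
#' dominated by that compartment's membrane current, which in turn is
#' dominated by the stimulus itself, so `|Ve| ~ I_stim / (4 pi sigma r)`:
#' frequency-independent by construction.
#'
#' @param iStim stimulation current amplitude, nA.
#' @param r distance, um (> 0).
#' @param sigma conductivity, S/m.
#' @return mV.
#' @export
nearFieldMonopole <- function(iStim, r, sigma = 0.3) {
  if (any(r <= 0)) stop("value error: r must be positive")
  iStim / (4 * pi * sigma * r)
}

#' Current-dipole moment of a cable solution
#'
#' `p(f) = sum_n im_n(f) (r_n - origin)` over compartment midpoints, nA um.
#' Requires conserved currents (`|sum im| <= 1e-6 max |im|`), which makes
#' the moment independent of `origin`.
#'
#' @param sol a [CableSolution-class].
#' @param morph the [Morphology-class] the solution was computed on.
#' @param origin 3-vector reference point, um (default: soma midpoint).
#' @return a [DipoleMoment-class].
#' @export
dipoleMoment <- function(sol, morph, origin = NULL) {
  if (is.null(origin)) origin <- midpoints(morph)[somaIndex(morph), ]
  imax <- max(abs(sol@im))
  if (imax > 0 && max(abs(colSums(sol@im))) > 1e-6 * imax)
    stop("conservation error: membrane currents do not sum to zero")
  mid <- sweep(midpoints(morph), 2L, origin)
  p <- t(mid) %*% sol@im    # 3 x F
  dimnames(p) <- NULL
  new("DipoleMoment", p = p, origin = as.numeric(origin),
      frequencies = sol@frequencies)
}

#' Far-field dipole approximation
#'
#' `Ve = |p| cos(theta) / (4 pi sigma r^2)` with `theta` the angle between
#' the dipole moment and the line from its origin to the observation point;
#' complex per frequency.
#'
#' @param p a [DipoleMoment-class].
#' @param obs 3-vector observation point, um.
#' @param sigma conductivity, S/m.
#' @return complex vector, one entry per frequency, mV.
#' @export
farFieldDipole <- function(p, obs, sigma = 0.3) {
  rvec <- obs - p@origin
  r <- sqrt(sum(rvec^2))
  if (r == 0) stop("singularity: observation point at dipole origin")
  ## p . rhat / (4 pi sigma r^2), valid componentwise for complex p
  as.vector(crossprod(p@p, rvec)) / (4 * pi * sigma * r^3)
}

#' Export a field map as columnar text
#'
#' Writes `x y z frequency amplitude phase` (tab-separated, um / Hz / mV /
#' radians) for each observation point and frequency.
#'
#' @param ve complex matrix as returned by [veFromSolution()].
#' @param obs matrix of observation points, um.
#' @param frequencies Hz.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFieldMap <- function(ve, obs, frequencies, path) {
  if (is.vector(obs)) obs <- matrix(obs, ncol = 3L)
  df <- do.call(rbind, lapply(seq_along(frequencies), function(k) {
    data.frame(x = obs[, 1], y = obs[, 2], z = obs[, 3],
               frequency = frequencies[k],
               amplitude = Mod(ve[, k]), phase = Arg(ve[, k]))
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
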
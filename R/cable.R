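## package-local state: linear-solve call counter (used to demonstrate the
## one-solve-per-frequency cost of the reciprocity route)
.cablert_state <- new.env(parent = emptyenv())
.cablert_state$solves <- 0L

#' Linear-solve call counter
#'
#' Every frequency-domain cable solve increments an internal counter. The
#' counter makes the computational advantage of the reciprocity route
#' checkable: predicting the response to stimulation from any number of
#' extracellular sites costs one solve per frequency, while the traditional
#' route costs one solve per site and frequency.
#'
#' @return `solveCount()` returns the number of linear solves since the last
#'   reset.
#' @export
solveCount <- function() .cablert_state$solves

#' @rdname solveCount
#' @export
resetSolveCount <- function() {
  .cablert_state$solves <- 0L
  invisible(NULL)
}

## per-compartment passive properties in internal units
## returns list(g uS, c nF, rhalf MOhm)
.membrane_tables <- function(morph, mem) {
  cp <- morph@compartments
  rm <- rep(mem@rm, nrow(cp)); cm <- rep(mem@cm, nrow(cp))
  for (k in names(mem@overrides)) {
    ov <- mem@overrides[[k]]
    sel <- cp$kind == k
    if (!is.null(ov$rm)) rm[sel] <- ov$rm
    if (!is.null(ov$cm)) cm[sel] <- ov$cm
  }
  area <- pi * cp$diameter * cp$length
  list(g = .membrane_conductance(area, rm),
       c = .membrane_capacitance(area, cm),
       rhalf = .axial_resistance(cp$length / 2, cp$diameter, mem@ra))
}

## axial coupling (graph Laplacian) in uS; axial conductance between a
## compartment and its parent is 1 / (sum of the two half-compartment axial
## resistances), the standard compartmental convention
.axial_laplacian <- function(morph, mem) {
  cp <- morph@compartments
  n <- nrow(cp)
  tb <- .membrane_tables(morph, mem)
  L <- matrix(0, n, n)
  for (i in seq_len(n)[-1L]) {
    p <- cp$parent[i]
    g <- 1 / (tb$rhalf[i] + tb$rhalf[p])
    L[i, p] <- L[i, p] - g
    L[p, i] <- L[p, i] - g
    L[i, i] <- L[i, i] + g
    L[p, p] <- L[p, p] + g
  }
  L
}

#' Assemble the frequency-domain cable operator
#'
#' Builds the complex admittance operator `A(f) = diag(Gm + i w C) + L` of
#' the passive compartmental cable system at one frequency, in uS: the
#' diagonal holds each compartment's membrane leak plus capacitive
#' admittance and its axial couplings, the off-diagonal entries the negated
#' axial conductances between adjacent compartments. The operator is
#' symmetric, and its row sums equal the per-compartment membrane admittance
#' (axial terms cancel).
#'
#' @param morph a [Morphology-class].
#' @param mem a [PassiveMembrane-class].
#' @param frequency Hz (>= 0; 0 gives the purely resistive DC operator).
#' @return a complex `n x n` matrix.
#' @export
assembleSystem <- function(morph, mem, frequency) {
  if (frequency < 0) stop("frequency must be >= 0")
  if (any(morph@compartments$length <= 0))
    stop("assembly error: zero-length compartment")
  tb <- .membrane_tables(morph, mem)
  L <- .axial_laplacian(morph, mem)
  ym <- complex(real = tb$g, imaginary = .omega_ms(frequency) * tb$c)
  L + diag(ym, nrow = length(ym))
}

## solve A x = b, counting
.cable_solve <- function(A, b) {
  .cablert_state$solves <- .cablert_state$solves + 1L
  sol <- tryCatch(solve(A, b), error = function(e)
    stop("numerical error: cable system is singular (", conditionMessage(e), ")"))
  sol
}

## complex stimulus amplitudes per frequency from a StimulusSpec
.stim_amplitudes <- function(stim) {
  stim@amplitude * exp(1i * stim@phases)
}

#' Solve the cable system for intracellular current injection
#'
#' Direct frequency-domain solve: one complex linear system per stimulus
#' frequency, giving the exact steady state with no transient truncation.
#' The stimulus is inward-positive (a positive amplitude depolarizes the
#' injected compartment). Membrane currents are outward-positive and include
#' the stimulus as part of the injected compartment's membrane current
#' (entering with sign `-I`), so that the currents of the whole cell sum to
#' zero at every frequency; the injected compartment then carries a net
#' membrane current close to `-I`, i.e. acts as the current sink balancing
#' the distributed return currents.
#'
#' @param morph a [Morphology-class].
#' @param mem a [PassiveMembrane-class].
#' @param site compartment index of the injection.
#' @param stim a [StimulusSpec-class] (see [sinusoidStimulus()],
#'   [multisineStimulus()]).
#' @return a [CableSolution-class].
#' @export
solveIntracellular <- function(morph, mem, site, stim) {
  n <- nCompartments(morph)
  if (site < 1L || site > n) stop("site out of range")
  amps <- .stim_amplitudes(stim)
  fs <- stim@frequencies
  tb <- .membrane_tables(morph, mem)
  vm <- matrix(0i, n, length(fs))
  im <- matrix(0i, n, length(fs))
  for (k in seq_along(fs)) {
    A <- assembleSystem(morph, mem, fs[k])
    rhs <- rep(0i, n); rhs[site] <- amps[k]
    v <- .cable_solve(A, rhs)
    ym <- complex(real = tb$g, imaginary = .omega_ms(fs[k]) * tb$c)
    i_m <- ym * v
    i_m[site] <- i_m[site] - amps[k]
    vm[, k] <- v
    im[, k] <- i_m
  }
  new("CableSolution", frequencies = fs, vm = vm, im = im,
      iin = amps, site = as.integer(site))
}

#' Solve the cable response to an imposed extracellular potential
#'
#' The traditional route to simulating extracellular stimulation: the
#' extracellular potential at every compartment midpoint enters the cable
#' system as a boundary condition, and the membrane-potential deviation is
#' driven by the spatial differences of that potential across adjacent
#' compartments (`(Ym + L) vm = -L ve`). A spatially uniform extracellular
#' potential therefore produces an identically zero response.
#'
#' @param morph a [Morphology-class].
#' @param mem a [PassiveMembrane-class].
#' @param veExt complex matrix (compartments x frequencies) of extracellular
#'   potentials at the compartment midpoints, mV. A vector is treated as a
#'   single-frequency column.
#' @param frequencies Hz, one per column of `veExt`.
#' @return a [CableSolution-class] holding the response (deviation from
#'   rest); its `im` are the induced membrane currents, which sum to zero.
#' @export
solveExtracellularStim <- function(morph, mem, veExt, frequencies) {
  n <- nCompartments(morph)
  if (is.vector(veExt)) veExt <- matrix(veExt, ncol = 1L)
  if (nrow(veExt) != n)
    stop("value error: veExt must have one row per compartment")
  if (ncol(veExt) != length(frequencies))
    stop("value error: one frequency per column of veExt required")
  tb <- .membrane_tables(morph, mem)
  L <- .axial_laplacian(morph, mem)
  vm <- matrix(0i, n, length(frequencies))
  im <- matrix(0i, n, length(frequencies))
  for (k in seq_along(frequencies)) {
    ym <- complex(real = tb$g, imaginary = .omega_ms(frequencies[k]) * tb$c)
    A <- L + diag(ym, nrow = n)
    v <- .cable_solve(A, -L %*% veExt[, k])
    vm[, k] <- v
    im[, k] <- ym * v
  }
  new("CableSolution", frequencies = frequencies, vm = vm, im = im,
      iin = NA_complex_, site = NA_integer_)
}

#' Input impedance
#'
#' Complex input impedance `Z(f) = Vm(site, f) / I` for a unit intracellular
#' injection, in MOhm. For passive membranes `|Z|` is non-increasing in
#' frequency.
#'
#' @param morph a [Morphology-class].
#' @param mem a [PassiveMembrane-class].
#' @param site compartment index.
#' @param frequencies Hz.
#' @return complex vector of impedances, MOhm.
#' @export
inputImpedance <- function(morph, mem, site, frequencies) {
  n <- nCompartments(morph)
  if (site < 1L || site > n) stop("site out of range")
  vapply(frequencies, function(f) {
    A <- assembleSystem(morph, mem, f)
    rhs <- rep(0i, n); rhs[site] <- 1 + 0i
    .cable_solve(A, rhs)[site]
  }, complex(1))
}
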
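#' Membrane-response map to extracellular stimulation via reciprocity
#'
#' The reciprocity route: the membrane-potential change of a target
#' compartment caused by an extracellular current source at location `r`
#' equals the extracellular potential at `r` generated by the same current
#' injected into the target compartment. One intracellular solve per
#' frequency therefore covers stimulation from any number of extracellular
#' sites; responses for an arbitrary stimulation amplitude are obtained by
#' scaling with the ratio of the extracellular to intracellular current
#' amplitude.
#'
#' @param solUnit a [CableSolution-class] from [solveIntracellular()] at the
#'   target compartment (any nonzero injection amplitude).
#' @param morph the morphology the solution was computed on.
#' @param obs extracellular stimulation locations: matrix of rows or a
#'   single 3-vector, um.
#' @param sigma conductivity, S/m.
#' @param iStim extracellular stimulation amplitude, nA.
#' @return complex matrix, locations x frequencies: membrane-potential
#'   deviation of the target compartment, mV.
#' @export
vmResponseMap <- function(solUnit, morph, obs, sigma = 0.3, iStim = 1) {
  iin <- solUnit@iin
  if (any(is.na(iin)) || any(Mod(iin) == 0))
    stop("value error: solUnit must come from an intracellular injection ",
         "with nonzero amplitude")
  ve <- veFromSolution(solUnit, morph, obs, sigma)
  sweep(ve, 2L, iStim / iin, `*`)
}

#' Relative error between two time series
#'
#' `SD(vEs - vRecip) / SD(vEs)`: the residual standard deviation of the
#' reciprocity-based prediction relative to the traditionally simulated
#' response.
#'
#' @param vEs reference time series (traditional solve).
#' @param vRecip predicted time series.
#' @return dimensionless error.
#' @export
relativeError <- function(vEs, vRecip) {
  if (length(vEs) != length(vRecip)) stop("series must have equal length")
  s <- stats::sd(vEs)
  if (s == 0) stop("undefined: SD of the reference series is zero")
  stats::sd(vEs - vRecip) / s
}

#' ES-proxy equivalent intracellular current
#'
#' The intracellular current that, injected alone, reproduces a given
#' membrane-potential response: `I_proxy(f) = dVm(f) / Z(f)`. Used to couple
#' the linear effect of extracellular stimulation into nonlinear point-model
#' simulations.
#'
#' @param deltaVm complex membrane-potential response per frequency, mV.
#' @param Z complex input impedance per frequency, MOhm (see
#'   [inputImpedance()]).
#' @return complex current per frequency, nA.
#' @export
esProxyCurrent <- function(deltaVm, Z) {
  if (length(deltaVm) != length(Z))
    stop("deltaVm and Z must have one entry per frequency")
  if (any(Mod(Z) == 0)) stop("value error: zero input impedance")
  deltaVm / Z
}

#' Reciprocity consistency check
#'
#' Runs both directions at one frequency - the traditional
#' extracellular-boundary-condition solve for a point source at `esPoint`,
#' and the reciprocity prediction from an intracellular injection at
#' `target` - and returns their relative discrepancy
#' `|vm_traditional - vm_reciprocity| / |vm_traditional|`. For passive
#' models the two are equal up to numerical round-off. When the traditional
#' response is degenerate (`|vm| < 1e-12` mV, e.g. for a stimulation site on
#' the zero-crossing surface of the field) the absolute discrepancy is
#' returned instead.
#'
#' @param morph a [Morphology-class].
#' @param mem a [PassiveMembrane-class].
#' @param target compartment index whose response is predicted.
#' @param esPoint 3-vector extracellular stimulation location, um.
#' @param sigma conductivity, S/m.
#' @param frequency Hz.
#' @param iStim stimulation amplitude, nA.
#' @return relative (or degenerate-case absolute) discrepancy.
#' @export
rtConsistencyCheck <- function(morph, mem, target, esPoint, sigma = 0.3,
                               frequency = 10, iStim = 1000) {
  ## traditional: impose the point-source potential as boundary condition
  veExt <- pointSourceKernel(morph, esPoint, sigma) * iStim
  solES <- solveExtracellularStim(morph, mem, veExt + 0i, frequency)
  vmES <- solES@vm[target, 1L]
  ## reciprocity: one intracellular solve at the target
  solIn <- solveIntracellular(morph, mem, target, sinusoidStimulus(frequency))
  vmRT <- vmResponseMap(solIn, morph, esPoint, sigma, iStim)[1L, 1L]
  if (Mod(vmES) < 1e-12) return(Mod(vmES - vmRT))
  Mod(vmES - vmRT) / Mod(vmES)
}
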
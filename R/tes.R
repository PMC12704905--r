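#' Somatic membrane response to transcranial stimulation across the cortex
#'
#' Reciprocity through the head model: the membrane-potential response of a
#' cell at cortical location `l` to a current `I_tes` through electrode `e`
#' equals the lead-field entry `M[e, l]` times the cell's current-dipole
#' moment per unit somatic input current (`T_ps`, um) times `I_tes`. The
#' spatial pattern across locations comes solely from the (frequency
#' independent) head model; the frequency dependence sits in `T_ps`.
#'
#' @param lead a [LeadField-class].
#' @param electrode electrode name or index.
#' @param Tps complex dipole transfer factor at the stimulation frequency,
#'   um (from [transferDipole()] or `dipoleMoment(...)/I_in`).
#' @param iTes stimulation amplitude, mA (a warning is issued above 10 mA,
#'   outside the documented safety range).
#' @return membrane-potential amplitude per cortical location, uV.
#' @export
tesVmMap <- function(lead, electrode, Tps, iTes = 1) {
  e <- .electrode_index(lead, electrode)
  if (iTes > 10)
    warning("tES amplitude above 10 mA: outside the documented safety range")
  ## M [mV / (nA um)] * |Tps| [um] * I [nA] -> mV; report uV
  lead@matrix[e, ] * Mod(Tps) * (iTes * 1e6) * 1e3
}

#' Cortical electric field from transcranial stimulation
#'
#' Reads the lead field in its reciprocal interpretation: entry `M[e, l]`
#' (mV/um per nA of electrode current) gives the electric field along the
#' cortical normal at location `l` per unit current through electrode `e`.
#' The membrane-response map of [tesVmMap()] is this field scaled by the
#' cell's `|T_ps|`.
#'
#' @param lead a [LeadField-class].
#' @param electrode electrode name or index.
#' @param iTes stimulation amplitude, mA.
#' @return a [CorticalField-class]; `Ecn` in mV/mm.
#' @export
corticalField <- function(lead, electrode, iTes = 1) {
  e <- .electrode_index(lead, electrode)
  ## mV/um per nA * nA -> mV/um; * 1e3 -> mV/mm
  ecn <- lead@matrix[e, ] * (iTes * 1e6) * 1e3
  new("CorticalField", Ecn = ecn, electrode = lead@electrodeNames[e],
      amplitude = iTes)
}

.electrode_index <- function(lead, electrode) {
  if (is.character(electrode)) {
    e <- match(electrode, lead@electrodeNames)
    if (is.na(e)) stop("unknown electrode: ", electrode)
  } else {
    e <- as.integer(electrode)
    if (e < 1L || e > nrow(lead@matrix)) stop("unknown electrode: ", electrode)
  }
  e
}

#' Extracellular potential of a quasi-uniform field over a morphology
#'
#' Under the quasi-uniform assumption the stimulation-induced field is
#' constant over a neuron's extent; the imposed extracellular potential at
#' each compartment is then `Ve = -E . (midpoint - reference)` with the soma
#' midpoint as reference (the potential decreases along the field
#' direction, `E = -grad V`). Feeding the result to
#' [solveExtracellularStim()] gives the stimulation response of the detailed
#' morphology.
#'
#' @param E electric-field 3-vector, mV/mm.
#' @param morph a [Morphology-class].
#' @return extracellular potential per compartment, mV.
#' @export
quasiUniformVe <- function(E, morph) {
  mid <- midpoints(morph)
  ref <- mid[somaIndex(morph), ]
  ## positions in um: mV/mm * um = 1e-3 mV
  -as.numeric(sweep(mid, 2L, ref) %*% E) * 1e-3
}
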
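#' @import methods
NULL

.section_kinds <- c("soma", "dendrite", "axon_node", "axon_myelin")

#' Compartmentalized neuron morphology
#'
#' An ordered chain/tree of cylindrical compartments. Compartment 1 is the
#' root (parent index `-1L`); every other compartment's parent index is
#' smaller than its own index, so the table is in topological order and the
#' connectivity is a tree. All coordinates are in micrometres.
#'
#' The `compartments` slot is a `data.frame` with columns
#' `x0, y0, z0` (start point), `x1, y1, z1` (end point), `diameter`, `length`
#' (all um), `kind` (one of `"soma"`, `"dendrite"`, `"axon_node"`,
#' `"axon_myelin"`) and `parent` (integer index, `-1` for the root).
#'
#' @slot compartments data.frame as described above.
#' @seealso [loadSWC()], [buildBallAndStick()], [buildMyelinatedAxon()],
#'   [refineMorphology()]
#' @export
setClass("Morphology", representation(compartments = "data.frame"))

setValidity("Morphology", function(object) {
  cp <- object@compartments
  need <- c("x0", "y0", "z0", "x1", "y1", "z1", "diameter", "length",
            "kind", "parent")
  if (!all(need %in% names(cp)))
    return(paste("missing columns:", paste(setdiff(need, names(cp)), collapse = ", ")))
  n <- nrow(cp)
  if (n < 1L) return("morphology must contain at least one compartment")
  if (sum(cp$parent == -1L) != 1L) return("exactly one root (parent -1) required")
  if (cp$parent[1L] != -1L) return("compartment 1 must be the root")
  if (n > 1L && any(cp$parent[-1L] >= seq_len(n)[-1L] | cp$parent[-1L] < 1L))
    return("parent index of every non-root compartment must be a smaller positive index")
  if (any(cp$length <= 0) || any(cp$diameter <= 0))
    return("all lengths and diameters must be strictly positive")
  if (!all(cp$kind %in% .section_kinds))
    return("unknown section kind")
  d <- sqrt((cp$x1 - cp$x0)^2 + (cp$y1 - cp$y0)^2 + (cp$z1 - cp$z0)^2)
  if (any(abs(d - cp$length) > 1e-9))
    return("length must equal the start-to-end Euclidean distance")
  TRUE
})

#' @describeIn Morphology constructor from a compartment table.
#' @param compartments data.frame of compartments (see class description).
#' @export
Morphology <- function(compartments) {
  compartments$parent <- as.integer(compartments$parent)
  rownames(compartments) <- NULL
  new("Morphology", compartments = compartments)
}

#' Passive membrane parameters
#'
#' Specific membrane resistance, axial resistivity and specific capacitance,
#' with optional per-section-kind overrides (e.g. a high-`rm`, low-`cm`
#' myelin sheath).
#'
#' @slot rm specific membrane resistance, Ohm cm^2.
#' @slot ra axial resistivity, Ohm cm.
#' @slot cm specific membrane capacitance, uF/cm^2.
#' @slot overrides named list; names are section kinds, values are lists with
#'   any of `rm`, `cm` replacing the defaults for that kind.
#' @export
setClass("PassiveMembrane",
         representation(rm = "numeric", ra = "numeric", cm = "numeric",
                        overrides = "list"))

setValidity("PassiveMembrane", function(object) {
  if (object@rm <= 0 || object@ra <= 0 || object@cm <= 0)
    return("rm, ra and cm must be strictly positive")
  if (length(object@overrides)) {
    if (is.null(names(object@overrides)) ||
        !all(names(object@overrides) %in% .section_kinds))
      return("override names must be section kinds")
    for (ov in object@overrides) {
      if (!all(names(ov) %in% c("rm", "cm")))
        return("overrides may set rm and cm only")
      if (any(unlist(ov) <= 0)) return("override values must be positive")
    }
  }
  TRUE
})

#' @describeIn PassiveMembrane constructor.
#' @param rm,ra,cm see slots.
#' @param overrides see slots.
#' @export
PassiveMembrane <- function(rm = 30000, ra = 150, cm = 1, overrides = list()) {
  new("PassiveMembrane", rm = rm, ra = ra, cm = cm, overrides = overrides)
}

#' Stimulus specification
#'
#' A single sinusoid or an equal-amplitude random-phase multisine current.
#' Phases of a multisine are drawn uniformly on `[0, 2 pi)` from `seed`.
#' The time-domain convention is `sum_k a * cos(2 pi f_k t + phase_k)`, i.e.
#' the complex amplitude at `f_k` is `a * exp(1i * phase_k)`.
#'
#' @slot kind `"sinusoid"` or `"multisine"`.
#' @slot frequencies Hz.
#' @slot amplitude amplitude per frequency component, nA.
#' @slot phases radians, one per frequency.
#' @slot seed integer seed used to draw multisine phases (NA for sinusoid).
#' @export
setClass("StimulusSpec",
         representation(kind = "character", frequencies = "numeric",
                        amplitude = "numeric", phases = "numeric",
                        seed = "integer"))

setValidity("StimulusSpec", function(object) {
  if (!object@kind %in% c("sinusoid", "multisine")) return("unknown stimulus kind")
  if (object@kind == "sinusoid" && length(object@frequencies) != 1L)
    return("a sinusoid has exactly one frequency")
  if (any(!is.finite(object@frequencies)) || any(object@frequencies < 0))
    return("frequencies must be finite and >= 0")
  if (length(object@phases) != length(object@frequencies))
    return("one phase per frequency required")
  TRUE
})

#' @describeIn StimulusSpec single sinusoid of amplitude `amplitude` nA.
#' @param frequency Hz.
#' @param amplitude nA.
#' @param phase radians.
#' @export
sinusoidStimulus <- function(frequency, amplitude = 1, phase = 0) {
  new("StimulusSpec", kind = "sinusoid", frequencies = frequency,
      amplitude = amplitude, phases = phase, seed = NA_integer_)
}

#' @describeIn StimulusSpec equal-amplitude multisine with seeded random phases.
#' @param frequencies Hz.
#' @param seed integer; phases are uniform on `[0, 2 pi)` drawn from this seed.
#' @export
multisineStimulus <- function(frequencies, amplitude = 1, seed = 1L) {
  phases <- local({
    rng <- .seeded_rng(seed)
    rng(length(frequencies)) * 2 * pi
  })
  new("StimulusSpec", kind = "multisine", frequencies = frequencies,
      amplitude = amplitude, phases = phases, seed = as.integer(seed))
}

## uniform(0,1) generator isolated from the global RNG stream
.seeded_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    x <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    x
  }
}

#' Frequency-domain cable solution
#'
#' Complex membrane-potential deviations and membrane currents per
#' compartment and frequency. Membrane currents are outward-positive and
#' include any intracellular stimulus as part of the injected compartment's
#' membrane current, so that they sum to zero across the cell at every
#' frequency (current conservation).
#'
#' @slot frequencies Hz.
#' @slot vm complex matrix, compartments x frequencies, mV.
#' @slot im complex matrix, compartments x frequencies, nA (outward positive).
#' @slot iin complex injected current per frequency, nA (NA when the solution
#'   stems from an extracellular drive).
#' @slot site integer index of the injected compartment (NA for extracellular
#'   drive).
#' @export
setClass("CableSolution",
         representation(frequencies = "numeric", vm = "matrix", im = "matrix",
                        iin = "complex", site = "integer"))

setValidity("CableSolution", function(object) {
  if (ncol(object@vm) != length(object@frequencies) ||
      ncol(object@im) != length(object@frequencies))
    return("vm/im must have one column per frequency")
  if (!identical(dim(object@vm), dim(object@im)))
    return("vm and im must have identical dimensions")
  imax <- max(abs(object@im))
  if (imax > 0) {
    s <- max(abs(colSums(object@im)))
    ## relative to the current scale, with a sub-fA absolute floor for
    ## degenerate cases (e.g. a single compartment whose net current is
    ## itself round-off)
    if (s > max(1e-9 * imax, 1e-12))
      return("membrane currents must sum to zero at every frequency")
  }
  TRUE
})

#' Current-dipole moment
#'
#' Complex 3-vector current-dipole moment per frequency, in nA um. When the
#' membrane currents sum to zero the moment is independent of the chosen
#' origin.
#'
#' @slot p complex matrix, 3 x frequencies, nA um.
#' @slot origin 3-vector, um.
#' @slot frequencies Hz.
#' @export
setClass("DipoleMoment",
         representation(p = "matrix", origin = "numeric", frequencies = "numeric"))

setValidity("DipoleMoment", function(object) {
  if (nrow(object@p) != 3L) return("p must be 3 x frequencies")
  if (length(object@origin) != 3L) return("origin must be a 3-vector")
  if (ncol(object@p) != length(object@frequencies))
    return("one dipole column per frequency required")
  TRUE
})

#' Volume conductor description
#'
#' Describes the extracellular medium: an infinite homogeneous medium of
#' conductivity `sigma`, a four-sphere head model (brain/CSF/skull/scalp), or
#' a precomputed lead field.
#'
#' @slot kind `"infinite_homogeneous"`, `"four_sphere"` or `"lead_field"`.
#' @slot sigma extracellular conductivity, S/m (infinite case).
#' @slot radii four strictly increasing shell radii, mm (four-sphere case).
#' @slot sigmas four shell conductivities, S/m (four-sphere case).
#' @slot leadField a [LeadField-class] object (lead-field case) or NULL.
#' @export
setClass("VolumeConductor",
         representation(kind = "character", sigma = "numeric",
                        radii = "numeric", sigmas = "numeric",
                        leadField = "ANY"))

setValidity("VolumeConductor", function(object) {
  if (!object@kind %in% c("infinite_homogeneous", "four_sphere", "lead_field"))
    return("unknown volume-conductor kind")
  if (object@kind == "infinite_homogeneous" && object@sigma <= 0)
    return("sigma must be positive")
  if (object@kind == "four_sphere") {
    if (length(object@radii) != 4L || length(object@sigmas) != 4L)
      return("four radii and four conductivities required")
    if (any(diff(object@radii) <= 0)) return("radii must be strictly increasing")
    if (any(object@sigmas <= 0)) return("conductivities must be positive")
  }
  TRUE
})

#' @describeIn VolumeConductor infinite homogeneous medium.
#' @param sigma conductivity, S/m.
#' @export
infiniteMedium <- function(sigma = 0.3) {
  new("VolumeConductor", kind = "infinite_homogeneous", sigma = sigma,
      radii = numeric(), sigmas = numeric(), leadField = NULL)
}

#' @describeIn VolumeConductor concentric four-sphere head model. Defaults:
#'   brain/CSF/skull/scalp radii 79, 80, 85, 90 mm and conductivities 0.276,
#'   1.65, 0.01, 0.465 S/m.
#' @param radii four shell radii, mm.
#' @param sigmas four shell conductivities, S/m.
#' @export
fourSphereModel <- function(radii = c(79, 80, 85, 90),
                            sigmas = c(0.276, 1.65, 0.01, 0.465)) {
  new("VolumeConductor", kind = "four_sphere", sigma = NA_real_,
      radii = radii, sigmas = sigmas, leadField = NULL)
}

#' Lead field matrix
#'
#' Linear map between current dipoles oriented along the local cortical
#' normal at each cortical location and the potential at each scalp
#' electrode. By reciprocity the same matrix entry, read the other way,
#' is the electric field along the cortical normal per unit electrode
#' current. Internal calibration: `matrix[e, l]` is mV per nA um of dipole,
#' equivalently mV/um per nA of electrode current.
#'
#' @slot matrix electrodes x locations, mV per (nA um).
#' @slot electrodePositions electrodes x 3, mm.
#' @slot locationPositions locations x 3, mm.
#' @slot normals locations x 3 unit cortical normals.
#' @slot electrodeNames character vector of electrode identifiers.
#' @export
setClass("LeadField",
         representation(matrix = "matrix", electrodePositions = "matrix",
                        locationPositions = "matrix", normals = "matrix",
                        electrodeNames = "character"))

setValidity("LeadField", function(object) {
  ne <- nrow(object@matrix); nl <- ncol(object@matrix)
  if (!all(is.finite(object@matrix))) return("lead field entries must be finite")
  if (nrow(object@electrodePositions) != ne || ncol(object@electrodePositions) != 3L)
    return("electrodePositions must be electrodes x 3")
  if (nrow(object@locationPositions) != nl || ncol(object@locationPositions) != 3L)
    return("locationPositions must be locations x 3")
  if (nrow(object@normals) != nl || ncol(object@normals) != 3L)
    return("normals must be locations x 3")
  if (length(object@electrodeNames) != ne)
    return("one name per electrode required")
  TRUE
})

#' @describeIn LeadField constructor.
#' @param matrix,electrodePositions,locationPositions,normals,electrodeNames
#'   see slots.
#' @export
LeadField <- function(matrix, electrodePositions, locationPositions, normals,
                      electrodeNames = paste0("E", seq_len(nrow(matrix)))) {
  new("LeadField", matrix = matrix,
      electrodePositions = as.matrix(electrodePositions),
      locationPositions = as.matrix(locationPositions),
      normals = as.matrix(normals), electrodeNames = electrodeNames)
}

#' Cortical electric field from transcranial stimulation
#'
#' Electric field along the cortical normal at each cortical location for a
#' given electrode and stimulation amplitude; linear in the amplitude.
#'
#' @slot Ecn field along the cortical normal, mV/mm, per location.
#' @slot electrode electrode identifier.
#' @slot amplitude tES current amplitude, mA.
#' @export
setClass("CorticalField",
         representation(Ecn = "numeric", electrode = "character",
                        amplitude = "numeric"))

#' Ball-and-stick model parameters
#'
#' Passive membrane parameters together with the geometry of a lumped
#' spherical soma (diameter `ds`) and an attached cylindrical dendritic
#' stick (length `l`, diameter `d`), for the closed-form transfer functions.
#'
#' @slot rm Ohm cm^2. @slot ra Ohm cm. @slot cm uF/cm^2.
#' @slot l stick length, um. @slot d stick diameter, um.
#' @slot ds soma diameter, um.
#' @export
setClass("BASParameters",
         representation(rm = "numeric", ra = "numeric", cm = "numeric",
                        l = "numeric", d = "numeric", ds = "numeric"))

setValidity("BASParameters", function(object) {
  v <- c(object@rm, object@ra, object@cm, object@d, object@ds)
  if (any(v <= 0)) return("all parameters must be strictly positive")
  if (object@l < 0) return("stick length must be >= 0")
  TRUE
})

#' @describeIn BASParameters constructor.
#' @param rm,ra,cm,l,d,ds see slots.
#' @export
BASParameters <- function(rm = 30000, ra = 150, cm = 1,
                          l = 1000, d = 2, ds = 10) {
  new("BASParameters", rm = rm, ra = ra, cm = cm, l = l, d = d, ds = ds)
}

## ---- show methods -------------------------------------------------------

setMethod("show", "Morphology", function(object) {
  cp <- object@compartments
  cat(sprintf("Morphology: %d compartments (%s)\n", nrow(cp),
              paste(sprintf("%s: %d", names(table(cp$kind)), table(cp$kind)),
                    collapse = ", ")))
  cat(sprintf("  total length %.1f um, total membrane area %.1f um^2\n",
              sum(cp$length), sum(pi * cp$diameter * cp$length)))
})

setMethod("show", "PassiveMembrane", function(object) {
  cat(sprintf("PassiveMembrane: Rm = %g Ohm cm^2, Ra = %g Ohm cm, Cm = %g uF/cm^2\n",
              object@rm, object@ra, object@cm))
  cat(sprintf("  tau_m = %.2f ms\n", .tau_m_ms(object@rm, object@cm)))
  for (k in names(object@overrides)) {
    ov <- object@overrides[[k]]
    cat(sprintf("  override %s: %s\n", k,
                paste(sprintf("%s = %g", names(ov), unlist(ov)), collapse = ", ")))
  }
})

setMethod("show", "CableSolution", function(object) {
  cat(sprintf("CableSolution: %d compartments x %d frequencies (%.3g-%.3g Hz)\n",
              nrow(object@vm), length(object@frequencies),
              min(object@frequencies), max(object@frequencies)))
  if (!is.na(object@site))
    cat(sprintf("  intracellular injection at compartment %d\n", object@site))
  else cat("  extracellular (boundary-condition) drive\n")
})

setMethod("show", "DipoleMoment", function(object) {
  cat(sprintf("DipoleMoment: %d frequencies, |p| = %s nA um\n",
              length(object@frequencies),
              paste(sprintf("%.3g", sqrt(colSums(abs(object@p)^2))), collapse = ", ")))
})

setMethod("show", "LeadField", function(object) {
  cat(sprintf("LeadField: %d electrodes x %d cortical locations [mV per nA um]\n",
              nrow(object@matrix), ncol(object@matrix)))
})

setMethod("show", "BASParameters", function(object) {
  cat(sprintf(
    "BASParameters: soma d_s = %g um, stick l = %g um, d = %g um\n",
    object@ds, object@l, object@d))
  cat(sprintf("  Rm = %g Ohm cm^2, Ra = %g Ohm cm, Cm = %g uF/cm^2 (lambda_DC = %.0f um)\n",
              object@rm, object@ra, object@cm, .lambda_um(object@d, object@rm, object@ra)))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for cableRT objects
#'
#' Small accessor generics: number of compartments, midpoints, membrane
#' areas, section kinds, solution spectra, etc.
#'
#' @param object a cableRT S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nCompartments", function(object) standardGeneric("nCompartments"))
#' @rdname accessors
#' @export
setMethod("nCompartments", "Morphology", function(object) nrow(object@compartments))

#' @rdname accessors
#' @export
setGeneric("compartments", function(object) standardGeneric("compartments"))
#' @rdname accessors
#' @export
setMethod("compartments", "Morphology", function(object) object@compartments)

#' @rdname accessors
#' @export
setGeneric("midpoints", function(object) standardGeneric("midpoints"))
#' @rdname accessors
#' @export
setMethod("midpoints", "Morphology", function(object) {
  cp <- object@compartments
  cbind(x = (cp$x0 + cp$x1) / 2, y = (cp$y0 + cp$y1) / 2, z = (cp$z0 + cp$z1) / 2)
})

#' @rdname accessors
#' @export
setGeneric("membraneAreas", function(object) standardGeneric("membraneAreas"))
#' @rdname accessors
#' @export
setMethod("membraneAreas", "Morphology", function(object) {
  cp <- object@compartments
  pi * cp$diameter * cp$length
})

#' @rdname accessors
#' @export
setGeneric("sectionKinds", function(object) standardGeneric("sectionKinds"))
#' @rdname accessors
#' @export
setMethod("sectionKinds", "Morphology", function(object) object@compartments$kind)

#' @rdname accessors
#' @export
setGeneric("somaIndex", function(object) standardGeneric("somaIndex"))
#' @rdname accessors
#' @details `somaIndex` returns the first soma compartment, or compartment 1
#'   when the morphology has no soma (e.g. an axon model).
#' @export
setMethod("somaIndex", "Morphology", function(object) {
  i <- which(object@compartments$kind == "soma")
  if (length(i)) i[1L] else 1L
})

#' @rdname accessors
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setMethod("frequencies", "CableSolution", function(object) object@frequencies)
#' @rdname accessors
#' @export
setMethod("frequencies", "DipoleMoment", function(object) object@frequencies)
#' @rdname accessors
#' @export
setMethod("frequencies", "StimulusSpec", function(object) object@frequencies)

#' @rdname accessors
#' @export
setGeneric("membranePotentials", function(object) standardGeneric("membranePotentials"))
#' @rdname accessors
#' @export
setMethod("membranePotentials", "CableSolution", function(object) object@vm)

#' @rdname accessors
#' @export
setGeneric("membraneCurrents", function(object) standardGeneric("membraneCurrents"))
#' @rdname accessors
#' @export
setMethod("membraneCurrents", "CableSolution", function(object) object@im)

#' @rdname accessors
#' @export
setGeneric("injectedCurrent", function(object) standardGeneric("injectedCurrent"))
#' @rdname accessors
#' @export
setMethod("injectedCurrent", "CableSolution", function(object) object@iin)

#' @rdname accessors
#' @export
setGeneric("momentVectors", function(object) standardGeneric("momentVectors"))
#' @rdname accessors
#' @export
setMethod("momentVectors", "DipoleMoment", function(object) object@p)

#' @rdname accessors
#' @export
setGeneric("leadMatrix", function(object) standardGeneric("leadMatrix"))
#' @rdname accessors
#' @export
setMethod("leadMatrix", "LeadField", function(object) object@matrix)

#' @rdname accessors
#' @export
setGeneric("electrodeNames", function(object) standardGeneric("electrodeNames"))
#' @rdname accessors
#' @export
setMethod("electrodeNames", "LeadField", function(object) object@electrodeNames)
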
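#' Read a lead field from a JSON file
#'
#' Plain-text lead-field layout used by this package: a JSON object with
#' named arrays
#' \describe{
#'   \item{`lead_field`}{electrodes x locations matrix, mV per nA um
#'     (normal-collapsed), or}
#'   \item{`lead_field_3c`}{electrodes x locations x 3 array, one slice per
#'     Cartesian dipole component, collapsed on load by projecting onto the
#'     location normals;}
#'   \item{`electrode_positions`}{electrodes x 3, mm;}
#'   \item{`location_positions`}{locations x 3, mm;}
#'   \item{`location_normals`}{locations x 3 unit cortical normals;}
#'   \item{`electrode_names`}{optional character vector.}
#' }
#' This mirrors the layout of published head-model lead fields (a
#' three-component electrode x location x orientation array plus electrode
#' and vertex coordinates and cortical normals, conventionally collapsed to
#' normal-oriented dipoles); converting such a file to this JSON layout is a
#' one-line export in any HDF5-capable tool. Matrix entries are calibrated
#' so that `matrix %*% p` with `p` in nA um yields electrode potentials in
#' mV; read reciprocally, an entry is the electric field along the cortical
#' normal (mV/um) per nA of electrode current.
#'
#' @param path JSON file path.
#' @return a [LeadField-class].
#' @export
loadLeadField <- function(path) {
  obj <- jsonlite::fromJSON(path)
  need <- c("electrode_positions", "location_positions", "location_normals")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("format error: missing named array '", miss[1L], "'")
  if (!is.null(obj[["lead_field"]])) {
    M <- as.matrix(obj[["lead_field"]])
  } else if (!is.null(obj[["lead_field_3c"]])) {
    arr <- obj[["lead_field_3c"]]        # electrodes x locations x 3
    nrm <- as.matrix(obj$location_normals)
    M <- arr[, , 1] * rep(nrm[, 1], each = dim(arr)[1]) +
         arr[, , 2] * rep(nrm[, 2], each = dim(arr)[1]) +
         arr[, , 3] * rep(nrm[, 3], each = dim(arr)[1])
    M <- matrix(M, nrow = dim(arr)[1])
  } else {
    stop("format error: missing named array 'lead_field'")
  }
  nm <- if (!is.null(obj$electrode_names)) obj$electrode_names
        else paste0("E", seq_len(nrow(M)))
  LeadField(M, as.matrix(obj$electrode_positions),
            as.matrix(obj$location_positions),
            as.matrix(obj$location_normals), nm)
}

#' Write a lead field to the package's JSON layout
#'
#' @param lead a [LeadField-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeLeadField <- function(lead, path) {
  obj <- list(
    lead_field = lead@matrix,
    electrode_positions = lead@electrodePositions,
    location_positions = lead@locationPositions,
    location_normals = lead@normals,
    electrode_names = lead@electrodeNames,
    units = "mV_per_nA_um")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Build a miniature lead field from the four-sphere head model
#'
#' Places `nLocations` dipole sites on a ring inside the brain shell (radial
#' cortical normals) and `nElectrodes` sites on the scalp, and fills the
#' matrix with the four-sphere potential of a unit normal-oriented dipole at
#' each location - a small but physically consistent lead field with the
#' same reciprocal reading as published head-model matrices.
#'
#' @param nElectrodes number of scalp electrodes.
#' @param nLocations number of cortical locations.
#' @param model a four-sphere [VolumeConductor-class].
#' @param depth dipole depth below the brain-shell surface, mm.
#' @param order series truncation order.
#' @return a [LeadField-class].
#' @export
makeLeadFieldFixture <- function(nElectrodes = 4L, nLocations = 10L,
                                 model = fourSphereModel(), depth = 15,
                                 order = 60L) {
  rl <- model@radii[1] - depth
  thL <- seq(0, pi / 2, length.out = nLocations)
  loc <- cbind(rl * sin(thL), 0, rl * cos(thL))
  nrm <- loc / rl
  re <- model@radii[4]
  thE <- seq(0, pi * 2 / 3, length.out = nElectrodes)
  ele <- cbind(re * sin(thE), 0, re * cos(thE))
  M <- matrix(0, nElectrodes, nLocations)
  for (l in seq_len(nLocations)) {
    M[, l] <- Re(fourSphereVe(nrm[l, ] + 0i, loc[l, ], ele, model, order))
  }
  LeadField(M, ele, loc, nrm)
}
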
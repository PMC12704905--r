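## SWC type codes <-> section kinds. Types 3 and 4 (basal/apical dendrite)
## both map to "dendrite"; the non-standard code 7 is used for myelinated
## internodes so that axon models round-trip.
.swc_to_kind <- function(type) {
  k <- rep("dendrite", length(type))
  k[type == 1] <- "soma"
  k[type == 2] <- "axon_node"
  k[type == 7] <- "axon_myelin"
  k
}

.kind_to_swc <- c(soma = 1L, axon_node = 2L, dendrite = 3L, axon_myelin = 7L)

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`), coordinates and
#' radii in micrometres (radii are converted to diameters, taken from the
#' child sample of each segment). One compartment is created per
#' parent-child sample pair. A compartment's section kind is the child
#' sample's type, except for compartments attached directly to the root
#' sample, which inherit the root's type (so a single-point soma still
#' yields a soma compartment). Coordinates are kept as-is (no re-centering).
#'
#' @param path path to an SWC file.
#' @return a [Morphology-class].
#' @export
loadSWC <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 7L)
  if (length(bad))
    stop("malformed SWC line ", lineno[bad[1L]], ": expected 7 columns")
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7L,
              byrow = TRUE)
  nab <- which(apply(m, 1L, function(r) any(is.na(r))))
  if (length(nab))
    stop("malformed SWC line ", lineno[nab[1L]], ": non-numeric field")
  colnames(m) <- c("id", "type", "x", "y", "z", "radius", "parent")
  ids <- m[, "id"]
  if (anyDuplicated(ids)) stop("duplicate sample id in SWC file")
  idx <- match(m[, "parent"], ids)            # NA for roots (-1)
  roots <- which(m[, "parent"] == -1)
  if (length(roots) != 1L)
    stop("structural error: expected exactly one root sample, found ",
         length(roots))
  unresolved <- which(m[, "parent"] != -1 & is.na(idx))
  if (length(unresolved))
    stop("structural error: parent of sample ", ids[unresolved[1L]],
         " not found")
  if (any(!is.na(idx) & idx >= seq_along(ids)))
    stop("structural error: parent sample must precede its child")
  child <- which(!is.na(idx))
  if (!length(child)) stop("SWC file has no segments")
  par <- idx[child]
  kind <- .swc_to_kind(m[child, "type"])
  rootKind <- .swc_to_kind(m[roots, "type"])
  kind[par == roots] <- rootKind
  ## compartment index of each sample = its position among child samples
  compOf <- integer(nrow(m)); compOf[child] <- seq_along(child)
  parentComp <- ifelse(par == roots, -1L, compOf[par])
  cp <- data.frame(
    x0 = m[par, "x"], y0 = m[par, "y"], z0 = m[par, "z"],
    x1 = m[child, "x"], y1 = m[child, "y"], z1 = m[child, "z"],
    diameter = 2 * m[child, "radius"],
    length = sqrt((m[child, "x"] - m[par, "x"])^2 +
                  (m[child, "y"] - m[par, "y"])^2 +
                  (m[child, "z"] - m[par, "z"])^2),
    kind = kind, parent = as.integer(parentComp))
  if (sum(cp$parent == -1L) != 1L)
    stop("structural error: samples do not form a single tree")
  Morphology(cp)
}

#' Write a morphology to an SWC file
#'
#' Inverse of [loadSWC()]: emits one root sample (the start point of the
#' root compartment) plus one sample per compartment end point.
#' `loadSWC(writeSWC(m, f))` reproduces the compartment table of `m`.
#'
#' @param morph a [Morphology-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSWC <- function(morph, path) {
  cp <- morph@compartments
  n <- nrow(cp)
  ## sample 1 = start of root compartment, sample i+1 = end of compartment i
  type <- .kind_to_swc[cp$kind]
  lines <- character(n + 1L)
  lines[1L] <- sprintf("1 %d %.9g %.9g %.9g %.9g -1",
                       type[1L], cp$x0[1L], cp$y0[1L], cp$z0[1L],
                       cp$diameter[1L] / 2)
  parentSample <- ifelse(cp$parent == -1L, 1L, cp$parent + 1L)
  for (i in seq_len(n)) {
    lines[i + 1L] <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                             i + 1L, type[i], cp$x1[i], cp$y1[i], cp$z1[i],
                             cp$diameter[i] / 2, parentSample[i])
  }
  writeLines(c("# generated by cableRT (id type x y z radius parent)", lines),
             path)
  invisible(path)
}
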
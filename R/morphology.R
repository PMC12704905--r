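#' Build a ball-and-stick morphology
#'
#' A lumped spherical soma plus a straight dendritic stick of `nSegments`
#' equal cylindrical compartments extending along +z. The soma is a single
#' iso-potential compartment whose membrane area equals that of a sphere of
#' diameter `somaDiameter` (modeled as a cylinder with length = diameter, so
#' the lateral area is `pi * ds^2`). The stick attaches at the soma midpoint
#' (the origin): because the soma is iso-potential its internal geometry only
#' sets its membrane area, and anchoring the stick base at the soma centre
#' matches the lumped-soma cable formalism used by the closed-form transfer
#' functions (see [transferSomaticCurrent()]).
#'
#' @param somaDiameter soma diameter `d_s`, um.
#' @param stickDiameter stick diameter `d`, um.
#' @param stickLength stick length `l`, um.
#' @param nSegments number of stick compartments (>= 1).
#' @return a [Morphology-class] with `nSegments + 1` compartments; compartment
#'   1 is the soma.
#' @examples
#' bas <- buildBallAndStick(10, 2, 1000, 100)
#' nCompartments(bas)  # 101
#' @export
buildBallAndStick <- function(somaDiameter, stickDiameter, stickLength,
                              nSegments) {
  if (somaDiameter <= 0 || stickDiameter <= 0 || stickLength <= 0)
    stop("all dimensions must be strictly positive")
  if (nSegments < 1L) stop("nSegments must be >= 1")
  dz <- stickLength / nSegments
  z0 <- c(-somaDiameter / 2, (seq_len(nSegments) - 1L) * dz)
  z1 <- c(somaDiameter / 2, seq_len(nSegments) * dz)
  cp <- data.frame(
    x0 = 0, y0 = 0, z0 = z0, x1 = 0, y1 = 0, z1 = z1,
    diameter = c(somaDiameter, rep(stickDiameter, nSegments)),
    length = c(somaDiameter, rep(dz, nSegments)),
    kind = c("soma", rep("dendrite", nSegments)),
    parent = c(-1L, 1L, utils::head(seq_len(nSegments) + 1L, -1L)))
  Morphology(cp)
}

#' Build a straight myelinated axon
#'
#' Alternating nodes of Ranvier and myelinated internodes along +z. The
#' number of nodes is `round(totalLength / nodeInterval)` (one node per
#' `nodeInterval` of axon); the first and the last compartment are nodes
#' (the terminal is a plain axon endpoint with the same diameter as the rest
#' of the axon), and the internodal myelin compartments fill the remaining
#' length in equal pieces.
#'
#' @param totalLength axon length, um.
#' @param nodeInterval spacing between consecutive nodes, um.
#' @param nodeLength length of a node of Ranvier, um.
#' @param diameter axon diameter, um (same for nodes and internodes).
#' @return a [Morphology-class]; section kinds alternate `axon_node` /
#'   `axon_myelin`.
#' @examples
#' ax <- buildMyelinatedAxon(10000, 50, 1, 1)
#' sum(sectionKinds(ax) == "axon_node")  # 200
#' @export
buildMyelinatedAxon <- function(totalLength, nodeInterval, nodeLength = 1,
                                diameter = 1) {
  if (nodeInterval >= totalLength) stop("nodeInterval must be < totalLength")
  if (nodeInterval <= nodeLength) stop("nodeInterval must exceed nodeLength")
  if (totalLength <= 0 || diameter <= 0 || nodeLength <= 0)
    stop("all dimensions must be strictly positive")
  nNodes <- max(2L, as.integer(round(totalLength / nodeInterval)))
  gap <- (totalLength - nNodes * nodeLength) / (nNodes - 1L)
  if (gap <= 0) stop("nodes do not fit in totalLength")
  lens <- numeric(2L * nNodes - 1L)
  kinds <- character(2L * nNodes - 1L)
  lens[seq(1L, length(lens), by = 2L)] <- nodeLength
  kinds[seq(1L, length(lens), by = 2L)] <- "axon_node"
  lens[seq(2L, length(lens), by = 2L)] <- gap
  kinds[seq(2L, length(lens), by = 2L)] <- "axon_myelin"
  z1 <- cumsum(lens)
  z0 <- c(0, utils::head(z1, -1L))
  n <- length(lens)
  cp <- data.frame(
    x0 = 0, y0 = 0, z0 = z0, x1 = 0, y1 = 0, z1 = z1,
    diameter = diameter, length = lens, kind = kinds,
    parent = c(-1L, seq_len(n - 1L)))
  Morphology(cp)
}

#' Refine a morphology to a maximum compartment length
#'
#' Splits every compartment longer than `maxLength` into equal pieces by
#' linear interpolation along its axis; diameters and section kinds are
#' inherited, so geometry, total cable length and total membrane area are
#' preserved exactly.
#'
#' @param morph a [Morphology-class].
#' @param maxLength maximum compartment length, um (> 0).
#' @return a refined [Morphology-class].
#' @export
refineMorphology <- function(morph, maxLength) {
  if (maxLength <= 0) stop("maxLength must be positive")
  cp <- morph@compartments
  nsplit <- pmax(1L, ceiling(cp$length / maxLength - 1e-12))
  ## map old index -> index of its last piece in the new table
  lastPiece <- cumsum(nsplit)
  rows <- vector("list", nrow(cp))
  for (i in seq_len(nrow(cp))) {
    k <- nsplit[i]
    f0 <- (seq_len(k) - 1L) / k
    f1 <- seq_len(k) / k
    par1 <- if (cp$parent[i] == -1L) -1L else lastPiece[cp$parent[i]]
    first <- lastPiece[i] - k + 1L
    rows[[i]] <- data.frame(
      x0 = cp$x0[i] + f0 * (cp$x1[i] - cp$x0[i]),
      y0 = cp$y0[i] + f0 * (cp$y1[i] - cp$y0[i]),
      z0 = cp$z0[i] + f0 * (cp$z1[i] - cp$z0[i]),
      x1 = cp$x0[i] + f1 * (cp$x1[i] - cp$x0[i]),
      y1 = cp$y0[i] + f1 * (cp$y1[i] - cp$y0[i]),
      z1 = cp$z0[i] + f1 * (cp$z1[i] - cp$z0[i]),
      diameter = cp$diameter[i],
      length = cp$length[i] / k,
      kind = cp$kind[i],
      parent = c(par1, if (k > 1L) first + seq_len(k - 1L) - 1L))
  }
  Morphology(do.call(rbind, rows))
}

#' Total cable length and membrane area
#'
#' @param morph a [Morphology-class].
#' @return um (length) or um^2 (area).
#' @export
totalLength <- function(morph) sum(morph@compartments$length)

#' @rdname totalLength
#' @export
totalArea <- function(morph) sum(membraneAreas(morph))

#' Generate a random branched passive morphology
#'
#' A soma plus a random tree of dendritic compartments grown by attaching
#' each new compartment to a uniformly chosen existing one, with random
#' direction, length and diameter. Used as a property-test generator: every
#' output satisfies the [Morphology-class] invariants by construction.
#'
#' @param seed integer seed (isolated from the global RNG stream).
#' @param nCompartments number of compartments including the soma.
#' @return a [Morphology-class].
#' @export
randomMorphology <- function(seed, nCompartments = 25L) {
  rng <- .seeded_rng(seed)
  somaD <- 8 + 8 * rng(1)
  cp <- data.frame(
    x0 = 0, y0 = 0, z0 = -somaD / 2, x1 = 0, y1 = 0, z1 = somaD / 2,
    diameter = somaD, length = somaD, kind = "soma", parent = -1L)
  for (i in seq_len(nCompartments - 1L)) {
    u <- rng(6)
    parent <- 1L + as.integer(floor(u[1] * nrow(cp) * 0.999999))
    len <- 20 + 60 * u[2]
    ct <- 2 * u[3] - 1            # cos(theta)
    st <- sqrt(1 - ct^2)
    ph <- 2 * pi * u[4]
    dirv <- c(st * cos(ph), st * sin(ph), ct)
    start <- if (cp$parent[parent] == -1L) {
      c((cp$x0[parent] + cp$x1[parent]) / 2,
        (cp$y0[parent] + cp$y1[parent]) / 2,
        (cp$z0[parent] + cp$z1[parent]) / 2)
    } else c(cp$x1[parent], cp$y1[parent], cp$z1[parent])
    cp <- rbind(cp, data.frame(
      x0 = start[1], y0 = start[2], z0 = start[3],
      x1 = start[1] + len * dirv[1], y1 = start[2] + len * dirv[2],
      z1 = start[3] + len * dirv[3],
      diameter = 0.5 + 3 * u[5], length = len, kind = "dendrite",
      parent = as.integer(parent)))
  }
  Morphology(cp)
}
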
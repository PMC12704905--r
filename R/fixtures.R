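#' Deterministic bundle of small test fixtures
#'
#' Generates, from a single seed, the small synthetic objects the test
#' surface runs on with no external downloads: a ball-and-stick cell, a
#' myelinated axon, a set of random branched morphologies, default passive
#' membranes (including a myelin override with a 40-fold increased membrane
#' resistance and 40-fold reduced capacitance, emulating the sheath), and a
#' miniature four-sphere-derived lead field.
#'
#' @param seed integer seed.
#' @param nRandom number of random branched morphologies.
#' @return named list with elements `ballAndStick`, `pyramidal` (a
#'   soma with an apical stick and four basal sticks, the package's
#'   multi-dendrite stand-in for a cortical pyramidal cell), `axon`,
#'   `random` (list), `membrane`, `axonMembrane`, `basParams`, `leadField`.
#' @export
fixtureSuite <- function(seed = 0L, nRandom = 5L) {
  list(
    ballAndStick = buildBallAndStick(10, 2, 1000, 100),
    pyramidal = .star_cell(),
    axon = buildMyelinatedAxon(10000, 50, 1, 1),
    random = lapply(seq_len(nRandom), function(i)
      randomMorphology(seed * 1000L + i, nCompartments = 20L + 2L * i)),
    membrane = PassiveMembrane(30000, 150, 1),
    axonMembrane = PassiveMembrane(
      30000, 150, 1,
      overrides = list(axon_myelin = list(rm = 30000 * 40, cm = 1 / 40))),
    basParams = BASParameters(30000, 150, 1, l = 1000, d = 2, ds = 10),
    leadField = makeLeadFieldFixture(4L, 10L)
  )
}

## Soma (10 um) with one apical stick along +z and four obliquely downward
## basal sticks (1000 um, 2 um each, 50 segments): a minimal multi-dendrite
## pyramidal-cell surrogate. Like the ball-and-stick, dendrites anchor at
## the iso-potential soma's midpoint.
.star_cell <- function(somaDiameter = 10, stickDiameter = 2,
                       stickLength = 1000, nSegments = 50L) {
  dirs <- rbind(c(0, 0, 1),
                c(1, 0, -0.3), c(-1, 0, -0.3),
                c(0, 1, -0.3), c(0, -1, -0.3))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  dz <- stickLength / nSegments
  cp <- data.frame(x0 = 0, y0 = 0, z0 = -somaDiameter / 2,
                   x1 = 0, y1 = 0, z1 = somaDiameter / 2,
                   diameter = somaDiameter, length = somaDiameter,
                   kind = "soma", parent = -1L)
  for (k in seq_len(nrow(dirs))) {
    base <- nrow(cp)
    s <- seq_len(nSegments)
    cp <- rbind(cp, data.frame(
      x0 = dirs[k, 1] * (s - 1) * dz, y0 = dirs[k, 2] * (s - 1) * dz,
      z0 = dirs[k, 3] * (s - 1) * dz,
      x1 = dirs[k, 1] * s * dz, y1 = dirs[k, 2] * s * dz,
      z1 = dirs[k, 3] * s * dz,
      diameter = stickDiameter, length = dz, kind = "dendrite",
      parent = as.integer(c(1L, base + s[-nSegments]))))
  }
  Morphology(cp)
}

#' Deterministic inventory digest of a fixture bundle
#'
#' A cheap reproducibility fingerprint: total lengths, areas and lead-field
#' column sums of every fixture, rounded and concatenated. Two bundles built
#' from the same seed produce identical digests.
#'
#' @param fx a bundle from [fixtureSuite()].
#' @return character scalar.
#' @export
fixtureDigest <- function(fx) {
  nums <- c(
    vapply(c(fx["ballAndStick"], fx["pyramidal"], fx["axon"], fx$random),
           function(m)
      c(totalLength(m), totalArea(m)), numeric(2)),
    colSums(fx$leadField@matrix))
  paste(sprintf("%.6e", nums), collapse = "|")
}

#' Export a cable solution as columnar text
#'
#' Writes `compartment x y z frequency vm_amplitude vm_phase im_amplitude`
#' (tab-separated; um, Hz, mV, radians, nA) for each compartment and
#' frequency.
#'
#' @param sol a [CableSolution-class].
#' @param morph the matching [Morphology-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSolution <- function(sol, morph, path) {
  mid <- midpoints(morph)
  df <- do.call(rbind, lapply(seq_along(sol@frequencies), function(k) {
    data.frame(compartment = seq_len(nrow(mid)),
               x = mid[, 1], y = mid[, 2], z = mid[, 3],
               frequency = sol@frequencies[k],
               vm_amplitude = Mod(sol@vm[, k]), vm_phase = Arg(sol@vm[, k]),
               im_amplitude = Mod(sol@im[, k]))
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
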
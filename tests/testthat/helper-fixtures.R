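## shared fixtures: default membrane, cells and small utilities

defaultMembrane <- function() PassiveMembrane(30000, 150, 1)

axonMembrane <- function() {
  PassiveMembrane(30000, 150, 1,
                  overrides = list(axon_myelin = list(rm = 30000 * 40,
                                                      cm = 1 / 40)))
}

defaultBAS <- function(n = 200) buildBallAndStick(10, 2, 1000, n)

defaultBASParams <- function() BASParameters(30000, 150, 1, 1000, 2, 10)

## single iso-potential spherical soma (diameter 10 um) as one compartment
isolatedSoma <- function(d = 10) {
  Morphology(data.frame(
    x0 = 0, y0 = 0, z0 = -d / 2, x1 = 0, y1 = 0, z1 = d / 2,
    diameter = d, length = d, kind = "soma", parent = -1L))
}

## straight two-compartment cable along z
twoCompCable <- function(len = 100, d = 2) {
  Morphology(data.frame(
    x0 = 0, y0 = 0, z0 = c(0, len), x1 = 0, y1 = 0, z1 = c(len, 2 * len),
    diameter = d, length = len, kind = "dendrite", parent = c(-1L, 1L)))
}

## log-log slope of |v| against r
logSlope <- function(r, v) {
  unname(stats::coef(stats::lm(log10(Mod(v)) ~ log10(r)))[2])
}

## minimal three-point SWC fixture (single-point soma + 2-point dendrite)
writeThreePointSWC <- function(path) {
  writeLines(c("# soma + two-point dendrite",
               "1 1 0 0 0 5 -1",
               "2 3 0 0 10 1 1",
               "3 3 0 0 30 1 2"), path)
  path
}
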
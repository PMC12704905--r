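test_that("point-source potential: value, 1/r decay, degenerate cases", {
  ## 1 uA at 50 um in sigma = 0.3 S/m
  expect_equal(vePointSource(1000, c(0, 0, 0), c(50, 0, 0), 0.3),
               1000 / (4 * pi * 0.3 * 50))
  expect_equal(vePointSource(0, c(0, 0, 0), c(50, 0, 0), 0.3), 0)
  v1 <- vePointSource(7, c(0, 0, 0), c(0, 20, 0), 0.3)
  v2 <- vePointSource(7, c(0, 0, 0), c(0, 40, 0), 0.3)
  expect_equal(v1 / v2, 2)
  expect_error(vePointSource(1, c(1, 2, 3), c(1, 2, 3), 0.3), "singularity")
  ## monopole helper is the same functional form
  expect_identical(nearFieldMonopole(12, 34, 0.3),
                   vePointSource(12, c(0, 0, 0), c(34, 0, 0), 0.3))
  expect_error(nearFieldMonopole(1, -1), "value error")
})

test_that("field of a solution reduces to a point source for one compartment", {
  mem <- defaultMembrane()
  soma <- isolatedSoma()
  sol <- solveIntracellular(soma, mem, 1, sinusoidStimulus(10))
  obs <- c(100, 50, 0)
  ve <- veFromSolution(sol, soma, obs, 0.3)
  im <- membraneCurrents(sol)[1, 1]
  expect_equal(ve[1, 1], vePointSource(im, midpoints(soma)[1, ], obs, 0.3))
})

test_that("near and far field approximations bracket the full sum", {
  mem <- defaultMembrane()
  bas <- defaultBAS(200)
  sol <- solveIntracellular(bas, mem, 1, sinusoidStimulus(1))
  dirv <- c(cos(-pi / 6), 0, sin(-pi / 6))
  ## close to the soma the full sum approaches the stimulus monopole, the
  ## more closely the nearer the observation point (return currents of the
  ## single thin stick keep the residual above 10% at 10 um)
  devAt <- function(r) {
    v <- Mod(veFromSolution(sol, bas, r * dirv, 0.3)[1, 1])
    abs(v / nearFieldMonopole(1, r, 0.3) - 1)
  }
  expect_lt(devAt(10), 0.15)
  expect_lt(devAt(6), devAt(10))
  expect_lt(devAt(10), devAt(20))
  ## at 100x the cell length the full sum is within 1% of the dipole term
  p <- dipoleMoment(sol, bas)
  robs <- 100 * 1000 * dirv
  vFar <- veFromSolution(sol, bas, robs, 0.3)[1, 1]
  vDip <- farFieldDipole(p, robs, 0.3)[1]
  expect_lt(Mod(vFar - vDip) / Mod(vDip), 0.01)
})

test_that("dipole moment: elementary pair, origin invariance, direct sum", {
  mem <- defaultMembrane()
  ## elementary two-point dipole from an antisymmetric extracellular drive
  m2 <- twoCompCable(100, 2)
  s2 <- solveExtracellularStim(m2, mem, c(1 + 0i, -1 + 0i), 10)
  im <- membraneCurrents(s2)[, 1]
  L <- diff(midpoints(m2)[, "z"])
  p2 <- dipoleMoment(s2, m2, origin = c(0, 0, 0))
  expect_equal(Mod(momentVectors(p2)[3, 1]), Mod(im[2]) * L)

  ## origin invariance and brute-force direct sum on random solutions
  for (seed in 1:10) {
    m <- randomMorphology(seed + 40, 20L)
    s <- solveIntracellular(m, mem, 2, sinusoidStimulus(25))
    pA <- dipoleMoment(s, m, origin = c(0, 0, 0))
    pB <- dipoleMoment(s, m, origin = c(513, -222, 97))
    expect_lt(max(Mod(momentVectors(pA) - momentVectors(pB))),
              1e-9 * max(Mod(momentVectors(pA))))
    ## oracle: explicit sum_n im_n r_n
    brute <- unname(t(midpoints(m)) %*% membraneCurrents(s))
    expect_equal(momentVectors(pA), brute)
  }
})

test_that("far-field dipole kernel: angle dependence and 1/r^2 decay", {
  p <- new("DipoleMoment", p = matrix(c(0, 0, 100 + 0i), 3, 1),
           origin = c(0, 0, 0), frequencies = 10)
  expect_equal(Mod(farFieldDipole(p, c(500, 0, 0), 0.3)), 0)  # theta = 90 deg
  vA <- farFieldDipole(p, c(0, 0, 1000), 0.3)
  vB <- farFieldDipole(p, c(0, 0, 2000), 0.3)
  expect_equal(Mod(vA) / Mod(vB), 4)
  expect_error(farFieldDipole(p, c(0, 0, 0), 0.3), "singularity")

  ## two-monopole exact sum vs dipole kernel on axis at r = 100 L
  L <- 10; I <- 5
  pd <- new("DipoleMoment", p = matrix(c(0, 0, I * L + 0i), 3, 1),
            origin = c(0, 0, 0), frequencies = 0)
  obs <- c(0, 0, 100 * L)
  exact <- vePointSource(I, c(0, 0, L / 2), obs, 0.3) +
    vePointSource(-I, c(0, 0, -L / 2), obs, 0.3)
  expect_lt(abs(Mod(farFieldDipole(pd, obs, 0.3)) / abs(exact) - 1), 0.005)
})

test_that("observation points inside a compartment are clamped to its radius", {
  mem <- defaultMembrane()
  soma <- isolatedSoma(10)
  sol <- solveIntracellular(soma, mem, 1, sinusoidStimulus(0))
  at_radius <- veFromSolution(sol, soma, c(5, 0, 0), 0.3)[1, 1]
  inside <- veFromSolution(sol, soma, c(1, 0, 0), 0.3)[1, 1]
  expect_equal(inside, at_radius)
})

test_that("field maps export as columnar text", {
  mem <- defaultMembrane()
  bas <- defaultBAS(20)
  sol <- solveIntracellular(bas, mem, 1, multisineStimulus(c(1, 100), seed = 2))
  obs <- rbind(c(20, 0, 0), c(0, 40, 10))
  ve <- veFromSolution(sol, bas, obs, 0.3)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeFieldMap(ve, obs, frequencies(sol), f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), 4L)
  expect_named(tab, c("x", "y", "z", "frequency", "amplitude", "phase"))
  expect_equal(tab$amplitude[1], Mod(ve[1, 1]))
})
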
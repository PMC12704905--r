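test_that("response map equals the traditional solve and scales with the stimulus", {
  mem <- defaultMembrane()
  bas <- defaultBAS(100)
  esPoint <- c(50, 0, 0)        # 50 um outside the soma
  f <- 10

  solIn <- solveIntracellular(bas, mem, 1, sinusoidStimulus(f))
  ## identity scaling: I_stim = I_in reproduces Ve at the point
  ve <- veFromSolution(solIn, bas, esPoint, 0.3)[1, 1]
  expect_equal(vmResponseMap(solIn, bas, esPoint, 0.3, iStim = 1)[1, 1], ve)

  ## equivalence with the extracellular-boundary-condition route
  iStim <- 1000
  dvmRT <- vmResponseMap(solIn, bas, esPoint, 0.3, iStim)[1, 1]
  veExt <- pointSourceKernel(bas, esPoint, 0.3) * iStim
  solES <- solveExtracellularStim(bas, mem, veExt + 0i, f)
  dvmES <- membranePotentials(solES)[1, 1]
  expect_lt(Mod(dvmES - dvmRT) / Mod(dvmES), 1e-8)
})

test_that("stimulation in the field's crossover plane has negligible effect", {
  mem <- defaultMembrane()
  bas <- defaultBAS(100)
  solIn <- solveIntracellular(bas, mem, 1, sinusoidStimulus(10))
  ## scan radially in the soma plane for the zero crossing of Re(Ve)
  zs <- seq(-50, 400, by = 2)
  ve <- vmResponseMap(solIn, bas, cbind(60, 0, zs), 0.3, 1)
  iz <- which(diff(sign(Re(ve[, 1]))) != 0)[1]
  expect_false(is.na(iz))
  crossPt <- c(60, 0, zs[iz])
  vAway <- Mod(vmResponseMap(solIn, bas, c(60, 0, -50), 0.3, 1)[1, 1])
  vCross <- Mod(vmResponseMap(solIn, bas, crossPt, 0.3, 1)[1, 1])
  expect_lt(vCross, 0.1 * vAway)
})

test_that("relative error: identical, null and scaled-sinusoid cases", {
  tms <- seq(0, 999)
  x <- sin(2 * pi * tms / 100)
  expect_equal(relativeError(x, x), 0)
  expect_equal(relativeError(x, rep(0, length(x))), 1)
  expect_equal(relativeError(x, 0.9 * x), 0.1)
  expect_error(relativeError(rep(1, 10), rep(0, 10)), "undefined")
  expect_error(relativeError(x, x[-1]), "equal length")
})

test_that("ES-proxy current inverts the input impedance and round-trips", {
  mem <- defaultMembrane()
  bas <- defaultBAS(100)
  f <- 10
  ## impedance reconstructed from a response/current pair: 2.1 mV from
  ## 67.6 pA means |Z| = 31.07 MOhm; the op must invert it
  Zpair <- 2.1 / 0.0676            # MOhm
  iProxy <- esProxyCurrent(2.1 + 0i, Zpair + 0i)
  expect_equal(Mod(iProxy), 0.0676, tolerance = 1e-12)
  expect_equal(esProxyCurrent(0 + 0i, Zpair + 0i), 0 + 0i)
  expect_error(esProxyCurrent(1 + 0i, 0 + 0i), "zero")

  ## round trip through the model: reinjecting I_proxy reproduces dVm
  Z <- inputImpedance(bas, mem, 1, f)
  dvm <- 2.1 * exp(0.4i)
  ip <- esProxyCurrent(dvm, Z)
  stim <- new("StimulusSpec", kind = "sinusoid", frequencies = f,
              amplitude = Mod(ip), phases = Arg(ip), seed = NA_integer_)
  back <- solveIntracellular(bas, mem, 1, stim)
  expect_lt(Mod(membranePotentials(back)[1, 1] - dvm) / Mod(dvm), 1e-9)
})

test_that("consistency check: degenerate normalization and mesh refinement", {
  mem <- defaultMembrane()
  bas <- defaultBAS(40)
  ## discrepancy does not grow under refinement
  d0 <- rtConsistencyCheck(bas, mem, 1, c(70, 10, 30), frequency = 100)
  basF <- refineMorphology(bas, 5)
  d1 <- rtConsistencyCheck(basF, mem, 1, c(70, 10, 30), frequency = 100)
  expect_lt(d0, 1e-8)
  expect_lt(d1, 1e-8)
})

test_that("stimulation always depolarizes some compartments and hyperpolarizes others", {
  mem <- defaultMembrane()
  bas <- defaultBAS(60)
  for (pt in list(c(40, 0, 200), c(-80, 30, 700), c(25, 25, -60))) {
    veExt <- pointSourceKernel(bas, pt, 0.3) * 1000
    sES <- solveExtracellularStim(bas, mem, veExt + 0i, 10)
    re <- Re(membranePotentials(sES)[, 1])
    expect_lt(min(re), 0)
    expect_gt(max(re), 0)
  }
})

test_that("one solve per frequency covers an arbitrary stimulation grid", {
  mem <- defaultMembrane()
  bas <- defaultBAS(30)
  grid <- as.matrix(expand.grid(x = seq(30, 120, by = 10),
                                y = seq(-50, 50, by = 10), z = 0))
  resetSolveCount()
  solIn <- solveIntracellular(bas, mem, 1, sinusoidStimulus(10))
  dvm <- vmResponseMap(solIn, bas, grid, 0.3, 1000)
  expect_identical(solveCount(), 1L)
  expect_equal(nrow(dvm), nrow(grid))
  ## traditional route: one solve per site
  resetSolveCount()
  for (i in seq_len(5)) {
    veExt <- pointSourceKernel(bas, grid[i, ], 0.3) * 1000
    invisible(solveExtracellularStim(bas, mem, veExt + 0i, 10))
  }
  expect_identical(solveCount(), 5L)
})
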
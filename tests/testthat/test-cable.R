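test_that("assembled operator: DC limit, symmetry, hand-computed coupling", {
  mem <- defaultMembrane()
  soma <- isolatedSoma(10)
  A <- assembleSystem(soma, mem, 0)
  expect_equal(dim(A), c(1L, 1L))
  expect_equal(Re(A[1, 1]), pi * 10^2 / 30000 * 1e-2)   # Gm of the sphere, uS
  expect_equal(Im(A[1, 1]), 0)

  ## symmetry on a branched morphology
  m <- randomMorphology(11, 30L)
  Af <- assembleSystem(m, mem, 137)
  expect_lt(max(Mod(Af - t(Af))), 1e-12 * max(Mod(Af)))
  ## row sums equal membrane admittances (axial terms cancel)
  tb <- cableRT:::.membrane_tables(m, mem)
  ym <- complex(real = tb$g, imaginary = cableRT:::.omega_ms(137) * tb$c)
  expect_equal(rowSums(Af), ym)

  ## two-compartment cable: off-diagonal = -1 / (sum of half axial resistances)
  m2 <- twoCompCable(100, 2)
  A2 <- assembleSystem(m2, mem, 0)
  rAx <- 2 * (4 * 150 * 50 * 1e-2 / (pi * 2^2))   # MOhm, hand computed
  expect_equal(Re(A2[1, 2]), -1 / rAx)
  expect_equal(A2[1, 2], A2[2, 1])
})

test_that("intracellular solve: Ohm's law, RC corner, conservation", {
  mem <- defaultMembrane()
  soma <- isolatedSoma(10)
  sol <- solveIntracellular(soma, mem, 1, sinusoidStimulus(0, amplitude = 1))
  rin <- 30000 / (pi * 10^2) * 1e2               # MOhm
  expect_equal(Re(membranePotentials(sol)[1, 1]), rin)

  ## corner frequency: |Z| drops by sqrt(2) at f = 1/(2 pi tau_m)
  fc <- 1 / (2 * pi * 0.030)                      # tau_m = 30 ms
  Z <- inputImpedance(soma, mem, 1, c(0, fc))
  expect_equal(Mod(Z[2]) / Mod(Z[1]), 1 / sqrt(2), tolerance = 1e-9)

  ## current conservation across frequencies and morphologies
  for (seed in 1:10) {
    m <- randomMorphology(seed, 20L)
    s <- solveIntracellular(m, mem, 1L + (seed %% 20L),
                            multisineStimulus(c(1, 10, 100, 1000), seed = seed))
    expect_lt(max(Mod(colSums(membraneCurrents(s)))),
              1e-9 * max(Mod(membraneCurrents(s))))
  }
})

test_that("frequency-domain solve matches the time-domain oracle to 0.1%", {
  mem <- defaultMembrane()
  bas <- defaultBAS(20)
  f <- 10
  stim <- makeMultisine(f, amplitude = 1, seed = 3, duration = 400, dt = 0.25)
  vt <- simulateTimeDomain(bas, mem, stim$current, 1, 0.25)
  keep <- stim$time >= 200                      # > 5 tau_m settling
  sp <- extractSpectrum(vt[1, keep], 0.25, frequencies = f)
  fd <- solveIntracellular(bas, mem, 1, sinusoidStimulus(f))
  expect_lt(abs(sp$amplitude / Mod(membranePotentials(fd)[1, 1]) - 1), 1e-3)
  ## input impedance against the same oracle
  Z <- inputImpedance(bas, mem, 1, f)
  expect_lt(abs(sp$amplitude / Mod(Z) - 1), 1e-3)
})

test_that("passive input impedance is low-pass across random morphologies", {
  mem <- defaultMembrane()
  for (seed in 1:50) {
    m <- randomMorphology(seed, 12L)
    Z <- inputImpedance(m, mem, 1, c(1, 10000))
    expect_lt(Mod(Z[2]), Mod(Z[1]))
  }
})

test_that("extracellular drive: uniform field nullity and antisymmetry", {
  mem <- defaultMembrane()
  bas <- defaultBAS(50)
  ## spatially uniform extracellular potential -> zero response
  sol <- solveExtracellularStim(bas, mem,
                                matrix(3.7 + 0i, nCompartments(bas), 1), 42)
  expect_lt(max(Mod(membranePotentials(sol))), 1e-12)

  ## antisymmetric drive on a symmetric two-compartment cable
  m2 <- twoCompCable()
  s2 <- solveExtracellularStim(m2, mem, c(1 + 0i, -1 + 0i), 10)
  vm <- membranePotentials(s2)
  expect_equal(vm[1, 1], -vm[2, 1])

  expect_error(solveExtracellularStim(m2, mem, c(1 + 0i), 10), "value error")
})

test_that("solutions are linear and obey superposition", {
  mem <- defaultMembrane()
  m <- randomMorphology(3, 20L)
  fs <- c(5, 50, 500)
  s1 <- solveIntracellular(m, mem, 4, multisineStimulus(fs, 1, seed = 9))
  s3 <- solveIntracellular(m, mem, 4, multisineStimulus(fs, 3, seed = 9))
  expect_equal(membranePotentials(s3), 3 * membranePotentials(s1))
  expect_equal(membraneCurrents(s3), 3 * membraneCurrents(s1))
  ## multisine response = per-frequency sinusoid responses
  spec <- multisineStimulus(fs, 1, seed = 9)
  for (k in seq_along(fs)) {
    sk <- solveIntracellular(m, mem, 4,
      new("StimulusSpec", kind = "sinusoid", frequencies = fs[k],
          amplitude = 1, phases = spec@phases[k], seed = NA_integer_))
    expect_lt(max(Mod(membranePotentials(sk)[, 1] -
                      membranePotentials(s1)[, k])),
              1e-10 * max(Mod(membranePotentials(s1)[, k])))
  }
})

test_that("operator-level reciprocity holds on random configurations", {
  mem <- defaultMembrane()
  rng <- cableRT:::.seeded_rng(2024)
  for (i in 1:20) {
    u <- rng(6)
    m <- randomMorphology(200 + i, 15L + as.integer(10 * u[1]))
    target <- 1L + as.integer(u[2] * (nCompartments(m) - 1L))
    pt <- c(300 * (u[3] - 0.5), 300 * (u[4] - 0.5), 300 * (u[5] - 0.5))
    f <- 10^(4 * u[6])
    ## Vm at target from extracellular unit current vs Ve at point from
    ## intracellular unit current
    veExt <- pointSourceKernel(m, pt, 0.3)
    sES <- solveExtracellularStim(m, mem, veExt + 0i, f)
    sIN <- solveIntracellular(m, mem, target, sinusoidStimulus(f))
    veRT <- veFromSolution(sIN, m, pt, 0.3)[1, 1]
    expect_lt(Mod(membranePotentials(sES)[target, 1] - veRT),
              1e-8 * Mod(veRT))
  }
})

test_that("spectrum extraction recovers amplitudes, phases and warns on leakage", {
  dt <- 0.1
  tms <- seq(0, 1000 - dt, by = dt)
  x <- 3 * cos(2 * pi * 10 * tms / 1000)
  sp <- extractSpectrum(x, dt, frequencies = 10)
  expect_equal(sp$amplitude, 3, tolerance = 1e-9)
  expect_equal(sp$phase, 0, tolerance = 1e-9)
  ## linearity: two components recovered independently
  y <- x + 1.5 * cos(2 * pi * 25 * tms / 1000 + 0.7)
  sp2 <- extractSpectrum(y, dt, frequencies = c(10, 25))
  expect_equal(sp2$amplitude, c(3, 1.5), tolerance = 1e-9)
  expect_equal(sp2$phase[2], 0.7, tolerance = 1e-8)
  expect_warning(extractSpectrum(y, dt, frequencies = 10.3), "leakage")
})
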
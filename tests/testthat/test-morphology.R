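test_that("ball-and-stick construction: counts, lengths and area conservation", {
  bas <- buildBallAndStick(10, 2, 1000, 100)
  expect_equal(nCompartments(bas), 101L)
  expect_equal(sectionKinds(bas)[1], "soma")
  stick <- compartments(bas)[-1, ]
  expect_equal(sum(stick$length), 1000)
  ## stick membrane area independent of discretization
  a1 <- totalArea(buildBallAndStick(10, 2, 1000, 1))
  a1000 <- totalArea(buildBallAndStick(10, 2, 1000, 1000))
  expect_equal(a1, a1000)
  ## soma area is that of a sphere of diameter ds
  expect_equal(membraneAreas(bas)[1], pi * 10^2)
  ## doubling l doubles summed stick length exactly
  bas2 <- buildBallAndStick(10, 2, 2000, 100)
  expect_equal(sum(compartments(bas2)$length[-1]),
               2 * sum(stick$length))
  expect_error(buildBallAndStick(-1, 2, 1000, 10), "positive")
})

test_that("myelinated axon: node counts and terminal convention", {
  ax <- buildMyelinatedAxon(10000, 50, 1, 1)
  kinds <- sectionKinds(ax)
  expect_equal(sum(kinds == "axon_node"), 200L)
  expect_equal(totalLength(ax), 10000)
  ax2 <- buildMyelinatedAxon(100, 50, 1, 1)
  expect_equal(sum(sectionKinds(ax2) == "axon_node"), 2L)
  ## first and last compartments are nodes
  expect_equal(kinds[1], "axon_node")
  expect_equal(kinds[length(kinds)], "axon_node")
  expect_error(buildMyelinatedAxon(10000, 1, 1, 1), "nodeLength")
  expect_error(buildMyelinatedAxon(100, 200, 1, 1), "totalLength")
})

test_that("refine bounds compartment length and preserves geometry", {
  stick <- buildBallAndStick(10, 2, 1000, 1)
  ref <- refineMorphology(stick, 10)
  expect_gte(nCompartments(ref), 100L)
  expect_true(all(compartments(ref)$length <= 10 + 1e-12))
  ## idempotence at equal splits
  expect_equal(compartments(refineMorphology(ref, 10)),
               compartments(ref))
  ## length/area preservation across random morphologies
  for (seed in 1:100) {
    m <- randomMorphology(seed, 15L)
    r <- refineMorphology(m, 13)
    expect_lt(abs(totalLength(r) / totalLength(m) - 1), 1e-9)
    expect_lt(abs(totalArea(r) / totalArea(m) - 1), 1e-9)
    expect_true(validObject(r))
  }
})

test_that("SWC reader: minimal tree, error reporting, round trip", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeThreePointSWC(f)
  m <- loadSWC(f)
  expect_equal(nCompartments(m), 2L)
  expect_equal(sectionKinds(m)[1], "soma")   # root segment inherits soma type
  expect_equal(compartments(m)$parent, c(-1L, 1L))

  ## parent referencing a later id -> structural error
  f2 <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 2", "2 3 0 0 10 1 -1"), f2)
  expect_error(loadSWC(f2), "structural|precede")

  ## malformed line named by number
  f3 <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 0 0 zz 1 1"), f3)
  expect_error(loadSWC(f3), "line 2")

  ## multiple roots
  f4 <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 1 50 0 0 5 -1", "3 3 0 0 10 1 1"), f4)
  expect_error(loadSWC(f4), "one root")

  ## round trip: write(load(f)) reparses to an identical compartment list
  f5 <- withr::local_tempfile(fileext = ".swc")
  writeSWC(m, f5)
  m2 <- loadSWC(f5)
  expect_equal(compartments(m2), compartments(m))

  ## round trip for an axon model (uses the myelin type code)
  ax <- buildMyelinatedAxon(500, 50, 1, 1)
  f6 <- withr::local_tempfile(fileext = ".swc")
  ax2 <- loadSWC(writeSWC(ax, f6))
  expect_equal(sectionKinds(ax2), sectionKinds(ax))
  expect_equal(totalLength(ax2), totalLength(ax))
})

test_that("morphology invariants are enforced", {
  cp <- compartments(defaultBAS(5))
  bad <- cp; bad$length[2] <- bad$length[2] * 2
  expect_error(Morphology(bad), "Euclidean")
  bad2 <- cp; bad2$parent[3] <- 5L
  expect_error(Morphology(bad2), "smaller")
  bad3 <- cp; bad3$diameter[1] <- 0
  expect_error(Morphology(bad3), "positive")
})

test_that("random morphology generator yields valid topologically ordered trees", {
  for (seed in 1:20) {
    m <- randomMorphology(seed, 30L)
    expect_true(validObject(m))
    p <- compartments(m)$parent
    expect_identical(p[1], -1L)
    expect_true(all(p[-1] < seq_len(30)[-1]))
  }
  ## deterministic in the seed
  expect_equal(compartments(randomMorphology(5)),
               compartments(randomMorphology(5)))
})
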
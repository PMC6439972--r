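test_that("solver refuses graphs without interaction candidates", {
  inst <- twoStrandFixture()
  g <- assignWeights(computeVertexEnergies(
    buildGraph(inst$strands, inst$structures, list())))
  expect_error(solveComplexes(g, solverConfig()), "interaction")
})

test_that("every archived clique is valid and its weight re-sums exactly", {
  for (seed in 1:15) {
    inst <- generateInstance(instanceSpec(seed = seed))
    g <- builtGraph(inst)
    arch <- solveComplexes(g, solverConfig(seed = seed, maxIterations = 60L,
                                           restarts = 2L))
    expect_gt(length(arch$members), 0L)
    w <- graphWeights(g)
    for (k in seq_along(arch$members)) {
      m <- arch$members[[k]]
      expect_true(isValidConstrainedClique(m, g))
      expect_identical(arch$weight[k], sum(w[m]))
    }
  }
})

test_that("archives are deterministic for a fixed seed and differ across seeds", {
  inst <- generateInstance(instanceSpec(seed = 8))
  g <- builtGraph(inst)
  a1 <- solveComplexes(g, solverConfig(seed = 5))
  a2 <- solveComplexes(g, solverConfig(seed = 5))
  expect_identical(a1$members, a2$members)
  expect_identical(a1$weight, a2$weight)
})

test_that("incremental move-set bookkeeping equals the from-scratch definitions", {
  for (seed in c(3L, 14L)) {
    inst <- generateInstance(instanceSpec(seed = seed))
    g <- builtGraph(inst)
    for (snap in blsMoveTrace(g, nMoves = 60L, seed = seed)) {
      ref <- cliqueSets(g, snap$members)
      expect_identical(sort(snap$PA), sort(as.integer(ref$PA)))
      expect_identical(sort(snap$OC), sort(as.integer(ref$OC)))
      expect_setequal(paste(snap$OM[, 1L], snap$OM[, 2L]),
                      paste(ref$OM[, "v"], ref$OM[, "u"]))
      expect_true(isValidConstrainedClique(snap$members, g))
      expect_equal(snap$weight, cliqueWeight(snap$members, g))
    }
  }
})

test_that("cliqueSets matches its definitions on hand-checkable states", {
  inst <- twoStrandFixture()
  g <- builtGraph(inst)
  inter <- which(g@kind == 1L)
  empties <- which(g@kind == 0L & g@nPairs == 0L)
  st <- cliqueSets(g, c(empties, inter))
  # the single interaction is inside C, so PA and OC are empty
  expect_length(st$PA, 0L)
  expect_length(st$OC, 0L)
  # each non-empty structure can replace its strand's empty structure
  expect_setequal(st$OM[, "v"], which(g@kind == 0L & g@nPairs > 0L))
})

test_that("solver finds the exhaustive optimum on small instances", {
  hits <- 0L
  for (seed in 101:115) {
    inst <- generateInstance(instanceSpec(seed = seed))
    g <- builtGraph(inst)
    arch <- solveComplexes(g, solverConfig(seed = seed))
    bf <- bruteForceOptimum(g, topK = 1L)
    hits <- hits + (abs(max(arch$weight) - bf$weight[1L]) < 1e-9)
    # the oracle bounds anything the heuristic archives
    expect_lte(max(arch$weight), bf$weight[1L] + 1e-9)
  }
  expect_gte(hits, 14L)
})

test_that("single-candidate graphs archive exactly the one valid complex", {
  ss <- StrandSet(c(A = "GGGG", B = "CCCC"))
  it <- list(interactionVertex("A", "B", cbind(0:3, 3:0)))
  g <- assignWeights(computeVertexEnergies(buildGraph(ss, list(), it)))
  arch <- solveComplexes(g, solverConfig(seed = 1, maxIterations = 20L))
  expect_length(arch$members, 1L)
  expect_setequal(arch$members[[1L]],
                  c(which(g@kind == 0L), which(g@kind == 1L)))
})
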
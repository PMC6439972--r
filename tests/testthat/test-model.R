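test_that("compatibility rule follows shared-nucleotide and same-strand logic", {
  ss <- StrandSet(c(A = "GGGAAACCCA", B = "GGGAAACCCA", C = "GGGAAACCCA"))
  sA1 <- structureVertex("A", cbind(0L, 9L))
  sA2 <- structureVertex("A", cbind(1L, 8L))
  emptyA <- structureVertex("A")
  iAB <- interactionVertex("A", "B", cbind(2L, 5L))
  iAC <- interactionVertex("A", "C", cbind(5L, 3L))

  # two structures on one strand: never compatible, even with disjoint pairs
  expect_false(areCompatible(sA1, sA2))
  expect_false(areCompatible(emptyA, sA1))
  # empty structure shares no nucleotide with anything off its strand class
  expect_true(areCompatible(emptyA, iAB))
  # shared nucleotide across kinds
  sA3 <- structureVertex("A", cbind(2L, 9L))
  expect_false(areCompatible(sA3, iAB))
  # interleaving but disjoint positions: crossing interactions permitted
  iAB2 <- interactionVertex("A", "B", cbind(1L, 8L))
  expect_true(areCompatible(iAB2, iAC))
})

test_that("compatibility is symmetric and matches an independent recomputation", {
  for (seed in c(11L, 12L)) {
    pool <- randomVertexPool(seed)
    for (a in seq_along(pool)) for (b in seq_along(pool)) {
      if (a == b) next
      expect_identical(areCompatible(pool[[a]], pool[[b]]),
                       areCompatible(pool[[b]], pool[[a]]))
      expect_identical(areCompatible(pool[[a]], pool[[b]]),
                       refCompatible(pool[[a]], pool[[b]]))
    }
  }
})

test_that("buildGraph adds empty structures, deduplicates, and materializes the edge set", {
  inst <- twoStrandFixture()
  g <- buildGraph(inst$strands, inst$structures, inst$interactions)
  # 2 given structures + 2 auto-empties + 1 interaction
  expect_equal(nVertices(g), 5L)
  expect_identical(g@adjacency, t(g@adjacency))
  expect_false(any(diag(g@adjacency)))
  # the edge set is exactly the compatibility relation
  for (i in seq_len(nVertices(g) - 1L)) for (j in (i + 1L):nVertices(g))
    expect_identical(g@adjacency[i, j],
                     areCompatible(g@vertices[[i]], g@vertices[[j]]))

  # duplicates collapse
  g2 <- buildGraph(inst$strands, c(inst$structures, inst$structures[1L]),
                   inst$interactions)
  expect_equal(nVertices(g2), 5L)
  # user-supplied empty collapses onto the auto-inserted one
  g3 <- buildGraph(inst$strands,
                   c(inst$structures, list(structureVertex("A"))),
                   inst$interactions)
  expect_equal(nVertices(g3), 5L)
})

test_that("misrouted candidates and unknown strands are rejected", {
  inst <- twoStrandFixture()
  expect_error(buildGraph(inst$strands, inst$interactions, list()),
               "StructureVertex")
  expect_error(buildGraph(inst$strands, list(), inst$structures),
               "InteractionVertex")
  expect_error(
    buildGraph(inst$strands, list(structureVertex("Z", cbind(0L, 5L))), inst$interactions),
    "unknown strand")
  expect_error(
    buildGraph(inst$strands, list(structureVertex("A", cbind(0L, 99L))), inst$interactions),
    "out of range")
})

test_that("constrained-clique validity demands one structure per strand and non-weakness", {
  inst <- twoStrandFixture()
  g <- builtGraph(inst)
  empties <- which(g@kind == 0L & g@nPairs == 0L)
  nonempty <- which(g@kind == 0L & g@nPairs > 0L)
  inter <- which(g@kind == 1L)
  # all-empty structures only: weak, not a complex
  expect_false(isValidConstrainedClique(empties, g))
  # one structure per strand + interaction, pairwise compatible
  expect_true(isValidConstrainedClique(c(empties, inter), g))
  expect_true(isValidConstrainedClique(c(nonempty, inter), g))
  # missing a strand's structure
  expect_false(isValidConstrainedClique(c(empties[1L], inter), g))
  # two structures on one strand is not even a clique
  expect_false(isValidConstrainedClique(c(empties[1L], nonempty[1L], empties[2L], inter), g))
})

test_that("clique weight is the exact member-weight sum", {
  inst <- twoStrandFixture()
  g <- builtGraph(inst)
  expect_identical(cliqueWeight(integer(0), g), 0)
  w <- graphWeights(g)
  members <- c(which(g@kind == 0L & g@nPairs > 0L), which(g@kind == 1L))
  expect_equal(cliqueWeight(members, g), sum(w[members]))
  # independent re-summation over the vertices owning each base pair
  resum <- sum(vapply(members, function(m) {
    v <- g@vertices[[m]]
    max(0, -vertexEnergy(v))
  }, 0))
  expect_equal(cliqueWeight(members, g), resum)
})

test_that("pseudoknot flag derives from the pair set", {
  v <- parseDotBracket("([)]", "A")
  expect_true(isPseudoknotted(v))
  expect_equal(vertexPairs(v)[, c("p1", "p2")],
               data.frame(p1 = c(0L, 1L), p2 = c(2L, 3L)),
               ignore_attr = TRUE)
  v2 <- parseDotBracket("([.])", "A")   # layered but nested: no crossing
  expect_false(isPseudoknotted(v2))
})
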
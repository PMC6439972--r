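test_that("symmetry classes group character-identical sequences", {
  ss <- StrandSet(c(A = "GGAC", B = "GGAC", C = "GUCC"))
  gr <- symmetryGroups(ss)
  expect_length(gr, 2L)
  expect_setequal(gr[[1L]], c("A", "B"))
  expect_identical(gr[[2L]], "C")
})

test_that("canonical form identifies symmetric complexes and is relabelling-invariant", {
  ss <- StrandSet(c(A = "GGAC", B = "GGAC", C = "GUCC"))
  gr <- symmetryGroups(ss)
  p1 <- vertexPairs(interactionVertex("A", "C", cbind(0L, 3L)))
  p2 <- vertexPairs(interactionVertex("B", "C", cbind(0L, 3L)))
  expect_identical(canonicalForm(p1, gr), canonicalForm(p2, gr))
  # distinct sequences: key is just the serialization
  grDistinct <- symmetryGroups(StrandSet(c(A = "GGAC", C = "GUCC")))
  expect_identical(canonicalForm(p1, grDistinct),
                   RNAComplexes:::.serializePairs(p1))

  # property: any within-class relabelling yields the same key
  set.seed(42)
  inst <- generateInstance(instanceSpec(duplicateStrands = TRUE, seed = 17))
  gr2 <- symmetryGroups(inst$strands)
  cls <- gr2[[which.max(lengths(gr2))]]
  pool <- c(inst$structures, inst$interactions)
  for (rep in 1:50) {
    v <- pool[[sample(length(pool), 1L)]]
    perm <- sample(cls)
    map <- stats::setNames(names(inst$strands), names(inst$strands))
    map[cls] <- perm
    relabeled <- RNAComplexes:::.relabelPairs(vertexPairs(v), map)
    expect_identical(canonicalForm(relabeled, gr2),
                     canonicalForm(vertexPairs(v), gr2))
  }
})

test_that("oversize symmetry classes fall back to identity with a warning", {
  ss <- StrandSet(stats::setNames(rep("GGAC", 4L), LETTERS[1:4]))
  gr <- symmetryGroups(ss)
  p <- vertexPairs(interactionVertex("A", "B", cbind(0L, 3L)))
  expect_warning(canonicalForm(p, gr, cap = 2L), "cap")
})

test_that("dedupAndRank sorts by energy, removes symmetric duplicates and truncates", {
  inst <- generateInstance(instanceSpec(duplicateStrands = TRUE, seed = 23))
  g <- builtGraph(inst)
  arch <- solveComplexes(g, solverConfig(seed = 23))
  preds <- dedupAndRank(arch, g, maxSolutions = 10L)
  expect_lte(length(preds), 10L)
  energies <- vapply(preds, function(p) p@energy, 0)
  expect_true(all(diff(energies) >= -1e-12))
  expect_identical(vapply(preds, function(p) p@rank, 0L), seq_along(preds))
  gr <- symmetryGroups(g@strands)
  keys <- vapply(preds, function(p) canonicalForm(p@pairs, gr), "")
  expect_false(anyDuplicated(keys) > 0L)
  # deduplication never merges genuinely distinct complexes
  plainKeys <- vapply(preds, function(p)
    RNAComplexes:::.serializePairs(p@pairs), "")
  expect_false(anyDuplicated(plainKeys) > 0L)
})

test_that("ranking handles explicit archives and empty input", {
  inst <- twoStrandFixture()
  g <- builtGraph(inst)
  arch <- solveComplexes(g, solverConfig(seed = 1))
  o <- order(arch$energy)
  expect_identical(dedupAndRank(arch, g, 3L)[[1L]]@energy, min(arch$energy))
  empty <- list(members = list(), weight = numeric(0), energy = numeric(0))
  expect_identical(dedupAndRank(empty, g), list())
})
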
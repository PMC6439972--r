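test_that("parameter resource is complete and canonical-only", {
  p <- turnerParams()
  expect_length(p$stack, 36L)
  duos <- c("AU", "UA", "GC", "CG", "GU", "UG")
  expect_setequal(names(p$stack),
                  as.vector(outer(duos, duos, function(a, b) paste0(a, "/", b))))
  expect_equal(p$hairpin[3L], 5.4)
  expect_true(all(is.infinite(p$hairpin[1:2])))   # loops < 3 are impossible
  expect_equal(unname(p$misc["duplex_init"]), 4.10)
})

test_that("stacking-sum model sums exactly the stacked adjacencies", {
  ss <- StrandSet(c(A = "GGGAAACCC", B = "GGUACC"))
  p <- turnerParams()
  helix <- structureVertex("A", cbind(0:2, 8:6))
  # hand-sum: two GG/CC stacks straight from the embedded table
  expect_identical(stackingSumEnergy(vertexPairs(helix), ss),
                   2 * unname(p$stack[["GC/GC"]]))
  # single pair anywhere: no stack exists
  expect_identical(stackingSumEnergy(vertexPairs(structureVertex("A", cbind(0L, 8L))), ss), 0)
  expect_identical(stackingSumEnergy(.emptyPairs(), ss), 0)
  # inter-strand stack (duplex geometry)
  iv <- interactionVertex("A", "B", cbind(0:1, 5:4))
  expect_identical(stackingSumEnergy(vertexPairs(iv), ss),
                   unname(p$stack[["GC/GC"]]))
  # adding an isolated canonical pair leaves the sum unchanged
  plus <- rbind(vertexPairs(helix), vertexPairs(interactionVertex("A", "B", cbind(3L, 2L))))
  plus <- plus[order(plus$s1, plus$p1), ]
  expect_identical(stackingSumEnergy(plus, ss),
                   stackingSumEnergy(vertexPairs(helix), ss))
  # non-canonical pair is a scoring error naming the offender
  ss2 <- StrandSet(c(A = "GAGAAACAC"))
  expect_error(stackingSumEnergy(vertexPairs(structureVertex("A", cbind(0L, 7L))), ss2),
               "non-canonical")
})

test_that("nearest-neighbor energies reproduce frozen reference values", {
  # values computed independently with a reference nearest-neighbor
  # evaluator (no dangles) on the same parameter release
  cases <- list(
    list(seq = "GGGAAACCC",  db = "(((...)))",   e = -1.20),  # stem + triloop
    list(seq = "AGGGAAACCCU", db = "((((...))))", e = -2.80), # terminal AU
    list(seq = "GGGAAACCCAAAGGGAAACCC",
         db = "(((...)))...(((...)))", e = -2.40),            # exterior loop
    list(seq = "GAGGGAAACCCC", db = "(.(((...))))", e = -0.70), # bulge of 1
    list(seq = "GAAGGGAAACCCC", db = "(..(((...))))", e = 1.60), # bulge of 2
    list(seq = "GGAGGGAAACCCAAGGGAAACCCACC",
         db = "((.(((...)))..(((...))).))", e = 0.90))        # multiloop
  for (cs in cases) {
    ss <- StrandSet(c(A = cs$seq))
    v <- parseDotBracket(cs$db, "A", ss)
    expect_equal(nnStructureEnergy(v, ss), cs$e, tolerance = 1e-9,
                 label = cs$db)
  }
  # empty structure scores exactly 0
  ss <- StrandSet(c(A = "GGGAAACCC"))
  expect_identical(nnStructureEnergy(structureVertex("A"), ss), 0)
})

test_that("nearest-neighbor stem-loop agrees with an external reference evaluator", {
  # RNAeval -d0 (ViennaRNA) as independent oracle on the same release
  skip_if(Sys.which("RNAeval") == "", "RNAeval not on PATH")
  seqs <- c("GGGAAACCC", "GCGAAACGC", "AGGGAAACCCU")
  dbs <- c("(((...)))", "(((...)))", "((((...))))")
  for (k in seq_along(seqs)) {
    out <- system2("RNAeval", "-d0", input = paste0(seqs[k], "\n", dbs[k]),
                   stdout = TRUE)
    refE <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)$", "\\1", out[2L]))
    ss <- StrandSet(c(A = seqs[k]))
    v <- parseDotBracket(dbs[k], "A", ss)
    expect_equal(nnStructureEnergy(v, ss), refE, tolerance = 0.1,
                 label = seqs[k])
  }
})

test_that("interaction energies are duplex initiation + stacks + gaps + terminal penalties", {
  p <- turnerParams()
  ss <- StrandSet(c(A = "GGGG", B = "CCCC", C = "AAAA"))
  # single G-C pair: initiation only
  expect_equal(interactionEnergy(interactionVertex("A", "B", cbind(0L, 3L)), ss),
               unname(p$misc["duplex_init"]))
  # single A-U pair: initiation + terminal AU at both duplex ends
  ssAU <- StrandSet(c(A = "AAAA", B = "UUUU"))
  expect_equal(interactionEnergy(interactionVertex("A", "B", cbind(0L, 3L)), ssAU),
               unname(p$misc["duplex_init"] + 2 * p$misc["terminal_au"]))
  # perfect 4-bp G/C duplex: initiation + 3 stacks
  expect_equal(interactionEnergy(interactionVertex("A", "B", cbind(0:3, 3:0)), ss),
               unname(p$misc["duplex_init"] + 3 * p$stack[["GC/GC"]]))
  # 1x1 internal loop inside the duplex
  ss2 <- StrandSet(c(A = "GAG", B = "CUC"))
  expect_equal(interactionEnergy(interactionVertex("A", "B", cbind(c(0L, 2L), c(2L, 0L))), ss2),
               unname(p$misc["duplex_init"] + p$internal[2L]))
  # interaction vertices cannot be empty by construction
  expect_error(interactionVertex("A", "B", matrix(integer(0), 0, 2)),
               "at least one pair")
})

test_that("model routing and weight assignment follow the energy conventions", {
  inst <- generateInstance(instanceSpec(seed = 21, pseudoknotProb = 1))
  g <- buildGraph(inst$strands, inst$structures, inst$interactions)
  g <- computeVertexEnergies(g)
  for (v in g@vertices) {
    if (is(v, "InteractionVertex"))
      expect_equal(vertexEnergy(v), interactionEnergy(v, g@strands))
    else if (isEmptyVertex(v))
      expect_identical(vertexEnergy(v), 0)
    else if (isPseudoknotted(v))
      expect_equal(vertexEnergy(v), stackingSumEnergy(vertexPairs(v), g@strands))
    else
      expect_equal(vertexEnergy(v), nnStructureEnergy(v, g@strands))
  }
  ssPk <- StrandSet(c(A = "GGGAAACCCAAAAA"))
  expect_error(nnStructureEnergy(parseDotBracket("([....)]......", "A", ssPk),
                                 ssPk), "pseudoknotted")

  g <- assignWeights(g)
  expect_identical(graphWeights(g), pmax(0, -graphEnergies(g)))
  # clamp examples
  gw <- function(e) max(0, -e)
  expect_identical(gw(-7.4), 7.4)
  expect_identical(gw(0), 0)
  expect_identical(gw(2.1), 0)
})

test_that("complex energy is the exact sum of member energies", {
  inst <- twoStrandFixture()
  g <- builtGraph(inst)
  arch <- solveComplexes(g, solverConfig(seed = 2, maxIterations = 50L,
                                         restarts = 1L))
  en <- graphEnergies(g)
  for (k in seq_along(arch$members))
    expect_identical(arch$energy[k], sum(en[arch$members[[k]]]))
})
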
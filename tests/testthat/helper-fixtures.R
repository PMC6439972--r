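# Shared fixture builders. Everything is constructed in code; no binary
# fixtures.

# two short strands plus one candidate of each kind, all disjoint
twoStrandFixture <- function() {
  ss <- StrandSet(c(A = "GGGAAACCCACGCG", B = "GCGUUAGGGAAACCC"))
  st <- list(parseDotBracket("(((...))).....", "A", ss),
             parseDotBracket("......(((...)))", "B", ss))
  it <- list(interactionVertex("A", "B", cbind(9:12, 3:0)))
  list(strands = ss, structures = st, interactions = it)
}

builtGraph <- function(inst) {
  assignWeights(computeVertexEnergies(
    buildGraph(inst$strands, inst$structures, inst$interactions)))
}

# independent recomputation of the compatibility rule, deliberately written
# differently from the package internals (explicit endpoint enumeration)
refCompatible <- function(u, v) {
  if (is(u, "StructureVertex") && is(v, "StructureVertex") &&
      u@strand == v@strand) return(FALSE)
  ends <- function(x) {
    p <- vertexPairs(x)
    unique(c(sprintf("%s@%d", p$s1, p$p1), sprintf("%s@%d", p$s2, p$p2)))
  }
  length(intersect(ends(u), ends(v))) == 0L
}

randomVertexPool <- function(seed) {
  inst <- generateInstance(instanceSpec(seed = seed))
  c(inst$structures, inst$interactions)
}
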
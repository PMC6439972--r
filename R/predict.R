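# End-to-end pipeline: candidates -> energies -> graph -> clique search ->
# symmetry dedup -> ranked complexes.

#' Predict ranked RNA complex secondary structures
#'
#' Combines candidate per-strand secondary structures and candidate
#' pairwise interaction sites into ranked whole-complex predictions:
#' energies are assigned to every candidate, the compatibility graph is
#' built, the constrained maximum-weight clique search is run, and the
#' archived cliques are deduplicated (symmetric copies arising from
#' identical sequences removed), sorted by total free energy and truncated.
#'
#' @param strands a \code{\link{StrandSet-class}}
#' @param structures list of \code{StructureVertex} candidates (several per
#'   strand; pseudoknotted candidates welcome)
#' @param interactions list of \code{InteractionVertex} candidates (several
#'   per strand pair); at least one is required, since a complex without
#'   any interaction site is not a complex
#' @param config a \code{\link{solverConfig}}
#' @param params energy parameters from \code{\link{turnerParams}}
#' @return ranked list of \code{\link{ComplexPrediction-class}}; the built
#'   graph is attached as attribute \code{"graph"} and the raw clique
#'   archive as attribute \code{"archive"}
#' @examples
#' ss <- StrandSet(c(A = "GGGAAACCCACGCGC", B = "GCGCGUAAGGGAAACCC"))
#' st <- list(parseDotBracket("(((...)))......", "A", ss),
#'            parseDotBracket("........(((...)))", "B", ss))
#' it <- list(interactionVertex("A", "B", cbind(9:14, 5:0)))
#' preds <- predictComplexes(ss, st, it, solverConfig(seed = 7))
#' preds[[1]]
#' @export
predictComplexes <- function(strands, structures, interactions,
                             config = solverConfig(),
                             params = turnerParams()) {
  g <- buildGraph(strands, structures, interactions)
  g <- computeVertexEnergies(g, params)
  g <- assignWeights(g)
  archive <- solveComplexes(g, config)
  preds <- dedupAndRank(archive, g, config@maxSolutions)
  attr(preds, "graph") <- g
  attr(preds, "archive") <- archive
  preds
}

#' File-to-file prediction run
#'
#' Reads the three input files (FASTA sequences, dot-bracket structure
#' candidates, interaction TSV), runs \code{\link{predictComplexes}}, and
#' writes the ranked report, the machine-readable TSV and a run manifest.
#' With \code{runs > 1}, the solver is executed \code{runs} times with
#' seeds derived from \code{config@seed} (seed, seed+1, ...), per-run
#' outputs are written with a \code{_run<k>} suffix, and the first run's
#' outputs keep the plain names; this mirrors repeated-execution protocols
#' used when benchmarking stochastic predictors.
#'
#' @param fastaPath,structurePath,interactionPath input files
#' @param outPrefix prefix for outputs: \code{<outPrefix>_complexes.txt},
#'   \code{<outPrefix>_complexes.tsv}, \code{<outPrefix>_manifest.txt}
#' @param config a \code{\link{solverConfig}}
#' @param runs number of repeated seeded executions
#' @return (invisibly) list of per-run prediction lists
#' @export
predictComplexFiles <- function(fastaPath, structurePath, interactionPath,
                                outPrefix, config = solverConfig(),
                                runs = 1L) {
  strands <- readStrands(fastaPath)
  structures <- readStructureCandidates(structurePath, strands)
  interactions <- readInteractionCandidates(interactionPath, strands)
  out <- vector("list", runs)
  for (k in seq_len(runs)) {
    cfg <- config
    cfg@seed <- config@seed + (k - 1L)
    preds <- predictComplexes(strands, structures, interactions, cfg)
    g <- attr(preds, "graph")
    suff <- if (k == 1L) "" else sprintf("_run%d", k)
    writeComplexes(preds, sprintf("%s_complexes%s.txt", outPrefix, suff), g)
    writePredictionsTSV(preds, sprintf("%s_complexes%s.tsv", outPrefix, suff))
    writeManifest(sprintf("%s_manifest%s.txt", outPrefix, suff), cfg,
                  inputs = c(fasta = fastaPath, structures = structurePath,
                             interactions = interactionPath),
                  outputs = c(report = sprintf("%s_complexes%s.txt",
                                               outPrefix, suff)))
    out[[k]] <- preds
  }
  invisible(out)
}
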
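# R surface of the clique-search heuristic.

#' Create a solver configuration
#'
#' @param maxIterations iterations per restart; one iteration is one
#'   descent to a local optimum followed by one perturbation
#' @param restarts number of independent searches (archives are merged)
#' @param seed integer seed driving every random choice of the solver
#' @param maxSolutions number of ranked complexes ultimately returned
#' @param lFrac perturbation strength as a fraction of the vertex count;
#'   the applied strength is \code{max(1, ceiling(lFrac * |V|))} moves
#' @param T non-improving descents tolerated before a strong perturbation
#' @param alphaS acceptance coefficient for degrading replacements: a
#'   degrading replace is kept only if it retains at least this fraction of
#'   the current clique weight
#' @param alphaR acceptance coefficient for removals: an interaction may
#'   leave only if its weight is at most \code{(1 - alphaR)} of the clique
#'   weight
#' @param phi tabu tenure: a vertex leaving the clique may not re-enter for
#'   this many iterations
#' @param p0 probability that a perturbation is directed (greedy over the
#'   least-degrading moves) rather than uniformly random
#' @return a \code{\link{SolverConfig-class}}
#' @export
solverConfig <- function(maxIterations = 500L, restarts = 5L, seed = 1L,
                         maxSolutions = 10L, lFrac = 0.1, T = 10L,
                         alphaS = 0.5, alphaR = 0.5, phi = 7L, p0 = 1) {
  new("SolverConfig", maxIterations = as.integer(maxIterations),
      restarts = as.integer(restarts), seed = as.integer(seed),
      maxSolutions = as.integer(maxSolutions), lFrac = lFrac,
      T = as.integer(T), alphaS = alphaS, alphaR = alphaR,
      phi = as.integer(phi), p0 = p0)
}

.graphHasWeights <- function(g) !anyNA(graphWeights(g))

#' Search the graph for high-weight constrained cliques
#'
#' Runs the breakout local search: from a random initial clique (one random
#' interaction plus one compatible structure per strand), alternate
#' best-improvement descent over add/replace moves with perturbation
#' (directed add/replace/remove moves under a tabu list, or a clique
#' restart after too many non-improving descents). Every distinct valid
#' clique encountered at any point, over all restarts, is archived; the
#' archive is the pool from which ranked optimal and sub-optimal complexes
#' are drawn.
#'
#' @param g a weighted \code{\link{CompatibilityGraph-class}}
#' @param config a \code{\link{solverConfig}}
#' @return the clique archive: a list with \code{members} (list of integer
#'   vertex-id vectors), \code{weight}, \code{energy} and \code{nPairs},
#'   one entry per distinct clique. Deterministic for a fixed seed.
#' @export
solveComplexes <- function(g, config = solverConfig()) {
  stopifnot(is(g, "CompatibilityGraph"), is(config, "SolverConfig"))
  if (!.graphHasWeights(g))
    stop("graph has unweighted vertices; run computeVertexEnergies() and assignWeights()")
  if (!any(g@kind == 1L))
    stop("no interaction candidates: an RNA complex needs at least one interaction site; supply interactions or use a single-RNA folding tool instead")
  res <- .bls_run(g@adjacency, g@kind,
                  ifelse(is.na(g@strandIndex), -1L, g@strandIndex - 1L),
                  graphWeights(g), g@nPairs, length(g@strands),
                  config@maxIterations, config@restarts, config@lFrac,
                  config@T, config@alphaS, config@alphaR, config@phi,
                  config@p0, as.double(config@seed))
  en <- graphEnergies(g)
  w <- graphWeights(g)
  # exact re-summation: the C++ search tracks weights incrementally for
  # speed, the archive reports the exact member-weight sums
  res$weight <- vapply(res$members, function(m) sum(w[m]), 0)
  res$energy <- vapply(res$members, function(m) sum(en[m]), 0)
  res$nPairs <- vapply(res$members, function(m) sum(g@nPairs[m]), 0L)
  class(res) <- "CliqueArchive"
  res
}

#' @export
print.CliqueArchive <- function(x, ...) {
  cat(sprintf("CliqueArchive: %d distinct valid clique(s); best weight %.3f\n",
              length(x$members),
              if (length(x$weight)) max(x$weight) else NA_real_))
  invisible(x)
}

#' Random move trace with incremental set maintenance
#'
#' Applies \code{nMoves} random legal moves (add / replace / remove, with
#' occasional clique restarts) starting from a random initial clique, and
#' returns after every move the clique together with the incrementally
#' maintained move sets PA, OM and OC. Intended for verifying the solver's
#' bookkeeping against the from-scratch definitions in
#' \code{\link{cliqueSets}}.
#'
#' @param g a weighted \code{\link{CompatibilityGraph-class}}
#' @param nMoves number of moves to apply
#' @param seed RNG seed
#' @return list of per-move snapshots (members, PA, OM, OC, weight)
#' @export
blsMoveTrace <- function(g, nMoves = 200L, seed = 1L) {
  stopifnot(is(g, "CompatibilityGraph"))
  if (!any(g@kind == 1L)) stop("no interaction candidates in graph")
  .bls_trace(g@adjacency, g@kind,
             ifelse(is.na(g@strandIndex), -1L, g@strandIndex - 1L),
             graphWeights(g), g@nPairs, length(g@strands),
             as.integer(nMoves), 7L, as.double(seed))
}
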
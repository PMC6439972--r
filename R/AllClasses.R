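#' @import methods
NULL

#' Set of RNA strands composing a complex candidate space
#'
#' A \code{StrandSet} is an ordered, named collection of RNA sequences, one
#' per strand of the complex under study. It extends
#' \code{\link[Biostrings]{RNAStringSet}}; names are the strand identifiers
#' and must be unique. Sequences are normalized to uppercase RNA (T is
#' converted to U on input).
#'
#' @seealso \code{\link{StrandSet}}, \code{\link{readStrands}}
#' @export
setClass("StrandSet", contains = "RNAStringSet")

setValidity("StrandSet", function(object) {
  ids <- names(object)
  if (is.null(ids) || any(is.na(ids)) || any(ids == ""))
    return("all strands must be named")
  if (anyDuplicated(ids))
    return(sprintf("duplicate strand id: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (any(Biostrings::width(object) < 1L))
    return("strand sequences must have length >= 1")
  bad <- grepl("[^ACGU]", as.character(object))
  if (any(bad))
    return(sprintf("strand %s contains non-ACGU characters",
                   ids[which(bad)[1L]]))
  TRUE
})

#' Candidate vertices of the compatibility graph
#'
#' A candidate vertex is either one secondary structure of a single strand
#' (\code{StructureVertex}) or one interaction site between two strands
#' (\code{InteractionVertex}). Both carry a set of base pairs, a free energy
#' in kcal/mol and a non-negative solver weight. Base pairs are stored as a
#' data.frame with columns \code{s1, p1, s2, p2} (strand id, 0-based
#' position), each row canonically ordered so that \code{(s1, p1) <= (s2,
#' p2)} lexicographically.
#'
#' @slot id integer vertex id (assigned by \code{\link{buildGraph}}; NA before).
#' @slot pairs data.frame of base pairs (columns \code{s1,p1,s2,p2}).
#' @slot energy free energy in kcal/mol (NA until computed).
#' @slot weight solver weight, \code{max(0, -energy)} (NA until assigned).
#'
#' @aliases StructureVertex-class InteractionVertex-class
#' @seealso \code{\link{structureVertex}}, \code{\link{interactionVertex}}
#' @export
setClass("CandidateVertex", representation("VIRTUAL",
  id = "integer", pairs = "data.frame",
  energy = "numeric", weight = "numeric"))

#' @describeIn CandidateVertex-class candidate secondary structure of one
#'   strand; \code{strand} names it and \code{pseudoknotted} records whether
#'   the pair set contains crossing pairs.
#' @slot strand single strand id (StructureVertex).
#' @slot pseudoknotted logical (StructureVertex).
#' @export
setClass("StructureVertex", contains = "CandidateVertex",
  representation(strand = "character", pseudoknotted = "logical"))

#' @describeIn CandidateVertex-class candidate interaction site between the
#'   two distinct strands in \code{strands}; every base pair has one endpoint
#'   on each, and the site itself is non-crossing (crossing interactions
#'   arise only between distinct vertices).
#' @slot strands the two strand ids (InteractionVertex).
#' @export
setClass("InteractionVertex", contains = "CandidateVertex",
  representation(strands = "character"))

.checkPairsFrame <- function(pairs) {
  need <- c("s1", "p1", "s2", "p2")
  if (!all(need %in% names(pairs)))
    return("pairs must have columns s1, p1, s2, p2")
  if (nrow(pairs)) {
    if (any(pairs$p1 < 0L) || any(pairs$p2 < 0L))
      return("positions must be >= 0 (0-based in memory)")
    swap <- pairs$s1 > pairs$s2 | (pairs$s1 == pairs$s2 & pairs$p1 >= pairs$p2)
    if (any(swap))
      return("pairs must be stored in canonical order (s1,p1) < (s2,p2)")
    keys <- c(paste(pairs$s1, pairs$p1), paste(pairs$s2, pairs$p2))
    if (anyDuplicated(keys))
      return("a nucleotide position occurs in more than one base pair")
  }
  TRUE
}

setValidity("StructureVertex", function(object) {
  if (length(object@strand) != 1L) return("exactly one strand id required")
  ok <- .checkPairsFrame(object@pairs)
  if (!isTRUE(ok)) return(ok)
  p <- object@pairs
  if (nrow(p) && any(p$s1 != object@strand | p$s2 != object@strand))
    return("structure base pairs must be internal to the vertex strand")
  if (length(object@pseudoknotted) == 1L && nrow(p) == 0L &&
      isTRUE(object@pseudoknotted))
    return("an empty structure cannot be pseudoknotted")
  TRUE
})

setValidity("InteractionVertex", function(object) {
  if (length(object@strands) != 2L || object@strands[1L] == object@strands[2L])
    return("an interaction involves exactly two distinct strands")
  ok <- .checkPairsFrame(object@pairs)
  if (!isTRUE(ok)) return(ok)
  p <- object@pairs
  if (nrow(p) == 0L) return("an interaction vertex must have at least one pair")
  ss <- sort(object@strands)
  if (any(p$s1 != ss[1L] | p$s2 != ss[2L]))
    return("every interaction pair must span exactly the two vertex strands")
  # antiparallel, non-crossing within a site: partner positions strictly
  # decrease as positions on the first strand increase
  o <- order(p$p1)
  if (nrow(p) > 1L && any(diff(p$p2[o]) >= 0L))
    return("interaction site contains crossing pairs")
  TRUE
})

#' Compatibility graph over candidate vertices
#'
#' Vertices are all candidate structures (one or more per strand, always
#' including an empty structure) and candidate interactions; an edge is
#' present exactly when two candidates are compatible, i.e. can coexist in
#' one complex (see \code{\link{areCompatible}}).
#'
#' @slot strands the \code{\link{StrandSet}}.
#' @slot vertices list of \code{CandidateVertex}, element i has id i.
#' @slot adjacency symmetric, irreflexive logical matrix.
#' @slot kind integer, 0 = structure, 1 = interaction.
#' @slot strandIndex for structure vertices, index of their strand in
#'   \code{strands}; NA for interactions.
#' @slot nPairs integer, number of base pairs per vertex.
#' @seealso \code{\link{buildGraph}}
#' @export
setClass("CompatibilityGraph", representation(
  strands = "StrandSet", vertices = "list", adjacency = "matrix",
  kind = "integer", strandIndex = "integer", nPairs = "integer"))

setValidity("CompatibilityGraph", function(object) {
  n <- length(object@vertices)
  a <- object@adjacency
  if (!is.logical(a) || nrow(a) != n || ncol(a) != n)
    return("adjacency must be an n x n logical matrix")
  if (n && !identical(a, t(a))) return("adjacency must be symmetric")
  if (n && any(diag(a))) return("adjacency must be irreflexive")
  if (length(object@kind) != n || length(object@strandIndex) != n ||
      length(object@nPairs) != n)
    return("kind, strandIndex and nPairs must have one entry per vertex")
  ids <- names(object@strands)
  for (i in seq_along(ids)) {
    empt <- object@kind == 0L & object@strandIndex == i & object@nPairs == 0L
    if (!any(empt))
      return(sprintf("strand %s lacks its empty structure vertex", ids[i]))
  }
  TRUE
})

#' Configuration of the clique-search heuristic
#'
#' Tuning constants of the breakout local search over the compatibility
#' graph. Defaults are the calibrated values used throughout:
#' perturbation strength \code{lFrac * |V|} moves (ceiling, minimum 1),
#' strong-perturbation threshold \code{T = 10} non-improving descents,
#' acceptance coefficients \code{alphaS = alphaR = 0.5}, tabu tenure
#' \code{phi = 7} iterations, directed-perturbation probability
#' \code{p0 = 1}, and 500 iterations per restart.
#'
#' @seealso \code{\link{solverConfig}}, \code{\link{solveComplexes}}
#' @export
setClass("SolverConfig", representation(
  maxIterations = "integer", restarts = "integer", seed = "integer",
  maxSolutions = "integer", lFrac = "numeric", T = "integer",
  alphaS = "numeric", alphaR = "numeric", phi = "integer", p0 = "numeric"))

setValidity("SolverConfig", function(object) {
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  if (object@restarts < 1L) return("restarts must be >= 1")
  if (object@maxSolutions < 1L) return("maxSolutions must be >= 1")
  if (object@lFrac <= 0) return("lFrac must be positive")
  if (object@T < 0L) return("T must be >= 0")
  if (object@alphaS < 0 || object@alphaS > 1 ||
      object@alphaR < 0 || object@alphaR > 1)
    return("alphaS and alphaR must lie in [0, 1]")
  if (object@phi < 0L) return("phi must be >= 0")
  if (object@p0 < 0 || object@p0 > 1) return("p0 must lie in [0, 1]")
  TRUE
})

#' One predicted RNA complex
#'
#' The complex denoted by a valid constrained clique: the union of the base
#' pairs of its member vertices, with total free energy equal to the sum of
#' the member energies (more negative = more stable) and its rank in the
#' energy-sorted output.
#'
#' @slot members integer vertex ids of the clique.
#' @slot pairs data.frame of all base pairs (columns \code{s1,p1,s2,p2}).
#' @slot energy total free energy, kcal/mol.
#' @slot weight total solver weight.
#' @slot rank 1-based position in the returned list.
#' @seealso \code{\link{predictComplexes}}, \code{\link{dedupAndRank}}
#' @export
setClass("ComplexPrediction", representation(
  members = "integer", pairs = "data.frame", energy = "numeric",
  weight = "numeric", rank = "integer"))
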
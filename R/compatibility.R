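# Graph construction: compatibility relation, constrained-clique predicates.

.pairedKeys <- function(v) {
  p <- v@pairs
  c(paste(p$s1, p$p1), paste(p$s2, p$p2))
}

#' @rdname areCompatible
setMethod("areCompatible", signature("CandidateVertex", "CandidateVertex"),
  function(u, v) {
    if (is(u, "StructureVertex") && is(v, "StructureVertex") &&
        u@strand == v@strand) return(FALSE)
    !any(.pairedKeys(u) %in% .pairedKeys(v))
  })

.vertexScope <- function(v) {
  if (is(v, "StructureVertex")) c("S", v@strand) else c("I", v@strands)
}

# identity used to collapse duplicate candidates: kind + strand scope + pairs
.vertexKey <- function(v) {
  p <- v@pairs
  paste(paste(.vertexScope(v), collapse = "|"),
        paste(p$s1, p$p1, p$s2, p$p2, sep = ":", collapse = ";"))
}

.checkVertexInSet <- function(v, strands) {
  ids <- names(strands)
  w <- Biostrings::width(strands)
  names(w) <- ids
  sc <- .vertexScope(v)[-1L]
  missing <- setdiff(sc, ids)
  if (length(missing))
    stop("vertex references unknown strand: ", paste(missing, collapse = ", "))
  p <- v@pairs
  if (nrow(p)) {
    out <- p$p1 >= w[p$s1] | p$p2 >= w[p$s2]
    if (any(out))
      stop(sprintf("base pair position out of range on strand %s",
                   p$s1[which(out)[1L]]))
  }
  invisible(TRUE)
}

#' Build the compatibility graph
#'
#' Assembles all candidate vertices into one graph: per-strand structure
#' candidates, inter-strand interaction candidates, plus one empty structure
#' per strand (energy 0, weight 0) guaranteeing that every strand can always
#' be covered. Duplicate candidates (same kind, strand scope and pair set)
#' are collapsed onto the first occurrence. The edge set is exactly the
#' pairwise compatibility relation.
#'
#' @param strands a \code{\link{StrandSet-class}}
#' @param structures list of \code{StructureVertex} (any order)
#' @param interactions list of \code{InteractionVertex}
#' @return a \code{\link{CompatibilityGraph-class}}; vertex ids are positions
#'   in its vertex list (structures grouped by strand first, each strand's
#'   empty vertex first, then interactions).
#' @export
buildGraph <- function(strands, structures = list(), interactions = list()) {
  stopifnot(is(strands, "StrandSet"))
  for (v in structures)
    if (!is(v, "StructureVertex"))
      stop("structures must be StructureVertex objects (a candidate spanning two strands is an interaction)")
  for (v in interactions)
    if (!is(v, "InteractionVertex"))
      stop("interactions must be InteractionVertex objects (a candidate internal to one strand is a structure)")
  lapply(structures, .checkVertexInSet, strands = strands)
  lapply(interactions, .checkVertexInSet, strands = strands)

  ids <- names(strands)
  ordered <- list()
  for (s in ids) {
    ordered <- c(ordered, list(structureVertex(s)),   # auto empty, energy 0
                 Filter(function(v) v@strand == s, structures))
  }
  ordered <- c(ordered, interactions)
  keys <- vapply(ordered, .vertexKey, "")
  ordered <- ordered[!duplicated(keys)]

  n <- length(ordered)
  kind <- integer(n); sidx <- rep(NA_integer_, n); np <- integer(n)
  for (i in seq_len(n)) {
    v <- ordered[[i]]
    v@id <- i
    ordered[[i]] <- v
    kind[i] <- if (is(v, "InteractionVertex")) 1L else 0L
    if (kind[i] == 0L) sidx[i] <- match(v@strand, ids)
    np[i] <- nrow(v@pairs)
  }
  adj <- matrix(FALSE, n, n)
  keysets <- lapply(ordered, .pairedKeys)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- if (kind[i] == 0L && kind[j] == 0L && sidx[i] == sidx[j]) FALSE
          else !any(keysets[[i]] %in% keysets[[j]])
    adj[i, j] <- adj[j, i] <- ok
  }
  new("CompatibilityGraph", strands = strands, vertices = ordered,
      adjacency = adj, kind = kind, strandIndex = sidx, nPairs = np)
}

#' Number of vertices in a compatibility graph
#' @param g a \code{CompatibilityGraph}
#' @export
nVertices <- function(g) length(g@vertices)

#' @rdname buildGraph
#' @param g a \code{CompatibilityGraph}
#' @export
graphWeights <- function(g) vapply(g@vertices, function(v) v@weight, 0)

#' @rdname buildGraph
#' @export
graphEnergies <- function(g) vapply(g@vertices, function(v) v@energy, 0)

#' Validity of a constrained clique
#'
#' A member set is a valid constrained clique iff its vertices are pairwise
#' compatible, there is exactly one structure vertex per strand, and the
#' total number of base pairs is positive (a clique whose members carry no
#' pairs at all -- a weak clique -- is not an RNA complex).
#'
#' @param members integer vertex ids
#' @param g the \code{CompatibilityGraph}
#' @return logical scalar
#' @export
isValidConstrainedClique <- function(members, g) {
  members <- as.integer(members)
  if (anyDuplicated(members) || any(members < 1L | members > nVertices(g)))
    return(FALSE)
  if (length(members) > 1L) {
    sub <- g@adjacency[members, members, drop = FALSE]
    if (!all(sub[upper.tri(sub)])) return(FALSE)
  }
  sVerts <- members[g@kind[members] == 0L]
  strandsCovered <- g@strandIndex[sVerts]
  if (length(sVerts) != length(names(g@strands)) ||
      anyDuplicated(strandsCovered) ||
      length(setdiff(seq_along(names(g@strands)), strandsCovered)))
    return(FALSE)
  sum(g@nPairs[members]) > 0L
}

#' Total weight of a clique
#'
#' @param members integer vertex ids (may be empty: weight 0)
#' @param g the \code{CompatibilityGraph}
#' @return the exact sum of member weights
#' @export
cliqueWeight <- function(members, g) {
  if (length(members) == 0L) return(0)
  sum(graphWeights(g)[as.integer(members)])
}

#' Solver move sets, computed from scratch
#'
#' From-scratch definitions of the three move sets driving the local
#' search, used as the reference the incremental solver bookkeeping is
#' checked against: \code{PA} is the interaction vertices outside the clique
#' adjacent to all of it; \code{OM} the same-kind pairs \code{(v, u)} with
#' \code{v} outside adjacent to all members except \code{u}; \code{OC} all
#' interaction vertices outside the clique.
#'
#' @param g a \code{CompatibilityGraph}
#' @param members integer vertex ids of the current clique
#' @return list with \code{PA} (integer vector), \code{OM} (two-column
#'   integer matrix, columns \code{v}, \code{u}) and \code{OC}
#' @export
cliqueSets <- function(g, members) {
  members <- as.integer(members)
  n <- nVertices(g)
  outside <- setdiff(seq_len(n), members)
  adjCount <- if (length(members))
    colSums(g@adjacency[members, , drop = FALSE]) else rep(0, n)
  PA <- outside[g@kind[outside] == 1L & adjCount[outside] == length(members)]
  omV <- integer(0); omU <- integer(0)
  for (v in outside[adjCount[outside] == length(members) - 1L]) {
    u <- members[!g@adjacency[v, members]]
    if (length(u) == 1L && g@kind[u] == g@kind[v]) {
      omV <- c(omV, v); omU <- c(omU, u)
    }
  }
  OC <- outside[g@kind[outside] == 1L]
  list(PA = PA, OM = cbind(v = omV, u = omU), OC = OC)
}

setMethod("show", "CompatibilityGraph", function(object) {
  cat(sprintf(
    "CompatibilityGraph: %d strand(s), %d structure + %d interaction vertices, %d edge(s)\n",
    length(object@strands), sum(object@kind == 0L), sum(object@kind == 1L),
    sum(object@adjacency) / 2L))
})
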
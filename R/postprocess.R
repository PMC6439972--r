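# From clique archive to ranked predictions: symmetry-aware deduplication,
# energy sorting, truncation.

#' Partition strands into symmetry classes
#'
#' Strands with character-identical sequences are interchangeable labels:
#' relabelling them maps one valid complex onto another (a symmetric
#' duplicate). The partition drives canonicalization and deduplication.
#'
#' @param strands a \code{\link{StrandSet-class}}
#' @return list of character vectors of strand ids; singleton classes
#'   included, classes disjoint and covering all strands
#' @export
symmetryGroups <- function(strands) {
  seqs <- as.character(strands)
  unname(split(names(strands), factor(seqs, levels = unique(seqs))))
}

.serializePairs <- function(pairs) {
  if (nrow(pairs) == 0L) return("")
  s <- sprintf("%s:%d-%s:%d", pairs$s1, pairs$p1, pairs$s2, pairs$p2)
  paste(sort(s), collapse = ";")
}

.relabelPairs <- function(pairs, map) {
  pairs$s1 <- unname(map[pairs$s1])
  pairs$s2 <- unname(map[pairs$s2])
  if (nrow(pairs)) {
    swap <- pairs$s1 > pairs$s2 | (pairs$s1 == pairs$s2 & pairs$p1 > pairs$p2)
    tmp <- pairs[swap, c("s2", "p2", "s1", "p1")]
    pairs[swap, c("s1", "p1", "s2", "p2")] <- tmp
  }
  pairs
}

.permutationMaps <- function(groups, cap) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (rest in perms(v[-k])) out <- c(out, list(c(v[k], rest)))
    out
  }
  ids <- unlist(groups)
  per.group <- lapply(groups, function(cls) {
    if (length(cls) > cap) {
      warning("symmetry class of ", length(cls),
              " identical strands exceeds cap ", cap,
              "; using identity relabelling only")
      return(list(cls))
    }
    perms(cls)
  })
  grid <- list(stats::setNames(character(0), character(0)))
  for (gi in seq_along(groups)) {
    cls <- groups[[gi]]
    grid <- unlist(lapply(grid, function(partial) {
      lapply(per.group[[gi]], function(p)
        c(partial, stats::setNames(p, cls)))
    }), recursive = FALSE)
  }
  grid
}

#' Canonical form of a complex under strand symmetry
#'
#' The lexicographically minimal serialization of the pair set over all
#' permutations of strand ids within each class of identical sequences.
#' Complexes differing only by relabelling identical strands share a
#' canonical form. Classes larger than \code{cap} fall back to the identity
#' permutation (with a warning) to avoid factorial blowup.
#'
#' @param pairs data.frame of base pairs (columns \code{s1,p1,s2,p2})
#' @param groups symmetry classes from \code{\link{symmetryGroups}}
#' @param cap largest class size canonicalized exactly
#' @return character scalar key
#' @export
canonicalForm <- function(pairs, groups, cap = 6L) {
  if (all(lengths(groups) == 1L)) return(.serializePairs(pairs))
  keys <- vapply(.permutationMaps(groups, cap),
                 function(map) .serializePairs(.relabelPairs(pairs, map)), "")
  min(keys)
}

.unionPairs <- function(g, members) {
  .sortPairs(do.call(rbind, c(lapply(g@vertices[members], function(v) v@pairs),
                              list(.emptyPairs()))))
}

#' Deduplicate and rank archived cliques
#'
#' Converts a clique archive into the returned predictions: one
#' representative per canonical form (lowest energy; ties keep the first
#' encountered), sorted by total free energy ascending (most stable first,
#' equal energies ordered by canonical key for determinism), truncated to
#' \code{maxSolutions}.
#'
#' @param archive a clique archive from \code{\link{solveComplexes}}
#' @param g the \code{\link{CompatibilityGraph-class}} it was computed on
#' @param maxSolutions maximum number of predictions returned
#' @param groups symmetry classes (default: computed from the graph strands)
#' @return list of \code{\link{ComplexPrediction-class}}, ranked
#' @export
dedupAndRank <- function(archive, g, maxSolutions = 10L,
                         groups = symmetryGroups(g@strands)) {
  nA <- length(archive$members)
  if (nA == 0L) return(list())
  pairsList <- lapply(archive$members, .unionPairs, g = g)
  keys <- vapply(pairsList, canonicalForm, "", groups = groups)
  best <- integer(0)
  bestOf <- new.env(parent = emptyenv())
  for (k in seq_len(nA)) {
    prev <- bestOf[[keys[k]]]
    if (is.null(prev) || archive$energy[k] < archive$energy[prev] - 1e-12)
      bestOf[[keys[k]]] <- k
  }
  reps <- unlist(as.list(bestOf))
  o <- order(archive$energy[reps], keys[reps])
  reps <- reps[o][seq_len(min(maxSolutions, length(reps)))]
  lapply(seq_along(reps), function(r) {
    k <- reps[r]
    new("ComplexPrediction", members = as.integer(archive$members[[k]]),
        pairs = pairsList[[k]], energy = archive$energy[k],
        weight = archive$weight[k], rank = as.integer(r))
  })
}

setMethod("show", "ComplexPrediction", function(object) {
  cat(sprintf("ComplexPrediction rank %s: %d vertices, %d base pair(s), energy %.2f kcal/mol\n",
              ifelse(is.na(object@rank), "-", object@rank),
              length(object@members), nrow(object@pairs), object@energy))
})

#' @rdname CandidateVertex-class
#' @export
setMethod("vertexPairs", "ComplexPrediction", function(x) x@pairs)

#' @rdname CandidateVertex-class
#' @export
setMethod("vertexEnergy", "ComplexPrediction", function(x) x@energy)
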
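# Random but structurally valid problem instances, and an exhaustive
# enumeration oracle for the constrained clique optimum. The generator
# stands in for the candidate-producing folding/hybridization tools: it
# emits helix-based candidates whose base pairs are canonical by
# construction (sequence letters are filled in to respect complementarity).

#' Describe a synthetic instance
#'
#' @param nStrands number of strands
#' @param lengthRange min/max strand length (nt; at least 20 when planting)
#' @param structuresPerStrand non-empty structure candidates per strand
#' @param interactionsPerPair interaction candidates per strand pair
#' @param pseudoknotProb probability that a structure candidate is built
#'   from two crossing helices (a pseudoknot) rather than one stem-loop
#' @param overlapProb probability that a candidate is anchored on
#'   positions already used by an earlier candidate, creating shared
#'   nucleotides and hence incompatibilities
#' @param duplicateStrands if TRUE, strand 2 is a copy of strand 1 and
#'   strand 1's candidates are mirrored onto it (exercises symmetry
#'   handling; not combinable with \code{plantOptimum}, whose optimum would
#'   no longer be unique)
#' @param plantOptimum if TRUE, one mutually compatible selection (a strong
#'   GC stem per strand plus a strong duplex) is constructed so that every
#'   other candidate is either weight-0 (short, destabilizing) or in
#'   conflict with the plant; the constrained optimum is then the plant,
#'   uniquely, by construction
#' @param seed RNG seed; a fixed seed reproduces the instance exactly
#' @return list of spec fields
#' @export
instanceSpec <- function(nStrands = 3L, lengthRange = c(20L, 40L),
                         structuresPerStrand = 4L, interactionsPerPair = 2L,
                         pseudoknotProb = 0.25, overlapProb = 0.3,
                         duplicateStrands = FALSE, plantOptimum = FALSE,
                         seed = 1L) {
  stopifnot(nStrands >= 2L, lengthRange[1L] >= 12L,
            lengthRange[2L] >= lengthRange[1L], structuresPerStrand >= 0L,
            interactionsPerPair >= 0L, pseudoknotProb >= 0,
            pseudoknotProb <= 1, overlapProb >= 0, overlapProb <= 1)
  if (isTRUE(plantOptimum) && lengthRange[1L] < 20L)
    stop("plantOptimum needs strands of at least 20 nt")
  if (isTRUE(plantOptimum) && isTRUE(duplicateStrands))
    stop("plantOptimum and duplicateStrands cannot be combined")
  if (isTRUE(duplicateStrands) && nStrands < 3L)
    stop("duplicateStrands needs at least 3 strands (interactions are mirrored through the non-duplicated strands)")
  list(nStrands = as.integer(nStrands), lengthRange = as.integer(lengthRange),
       structuresPerStrand = as.integer(structuresPerStrand),
       interactionsPerPair = as.integer(interactionsPerPair),
       pseudoknotProb = pseudoknotProb, overlapProb = overlapProb,
       duplicateStrands = isTRUE(duplicateStrands),
       plantOptimum = isTRUE(plantOptimum), seed = as.integer(seed))
}

# complement choice keeping pairs canonical. strength: "gc" only G-C pairs
# (guaranteed-stable planted helices), "strong" GC-rich, "any" full range
.complementOf <- function(nt, strength) {
  switch(nt,
         A = "U",
         U = if (strength != "any" || stats::runif(1) < 0.7) "A" else "G",
         G = "C",
         C = "G")
}

.pairDuos <- function(strength) {
  switch(strength,
         gc = c("GC", "CG"),
         strong = c("GC", "CG", "GC", "CG", "AU", "UA"),
         any = c("GC", "CG", "AU", "UA", "GU", "UG"))
}

# assign letters for pair (p, q) in a letters vector (1-based positions);
# returns updated letters, or NULL if both are fixed and non-canonical
.fillPair <- function(letters, p, q, strength = "strong") {
  a <- letters[p]; b <- letters[q]
  if (is.na(a) && is.na(b)) {
    duo <- sample(.pairDuos(strength), 1L)
    letters[p] <- substr(duo, 1L, 1L); letters[q] <- substr(duo, 2L, 2L)
  } else if (is.na(b)) {
    letters[q] <- .complementOf(a, strength)
  } else if (is.na(a)) {
    letters[p] <- .complementOf(b, strength)
  } else if (!paste0(a, b) %in% .canonicalPairs) {
    return(NULL)
  }
  letters
}

# pick a stem location: L pairs (i+t, j-t), hairpin loop >= 3. anchor:
# optionally start on/near positions already used, forcing shared
# nucleotides with an earlier candidate
.placeStem <- function(len, L, used, overlap) {
  span <- 2L * L + 3L
  if (len < span) return(NULL)
  starts <- seq_len(len - span + 1L)
  if (overlap && length(used)) {
    anch <- if (length(used) == 1L) used else sample(used, 1L)
    starts <- starts[starts <= anch & starts + L - 1L >= anch]
    if (!length(starts)) starts <- seq_len(len - span + 1L)
  }
  i <- if (length(starts) == 1L) starts else sample(starts, 1L)
  jmax <- len
  j <- if (i + span - 1L >= jmax) jmax else sample((i + span - 1L):jmax, 1L)
  cbind(i + 0:(L - 1L), j - 0:(L - 1L))      # 1-based
}

#' Generate a random valid instance
#'
#' Builds random sequences plus helix-based candidate structures and
#' interaction sites (see \code{\link{instanceSpec}}). Candidates are valid
#' by construction: canonical pairs (letters filled in to match), no
#' position paired twice within a candidate, non-crossing interaction
#' sites. The overlap knob injects shared nucleotides between candidates to
#' create incompatibilities; the pseudoknot knob emits crossing two-helix
#' structures scored by the stacking-sum model downstream.
#'
#' @param spec from \code{\link{instanceSpec}}
#' @return list with \code{strands} (\code{\link{StrandSet-class}}),
#'   \code{structures} (list of StructureVertex), \code{interactions}
#'   (list of InteractionVertex), and \code{planted} (NULL, or the planted
#'   selection as \code{list(structures, interactions)})
#' @export
generateInstance <- function(spec = instanceSpec()) {
  set.seed(spec$seed)
  n <- spec$nStrands
  ids <- LETTERS[seq_len(n)]
  lens <- sample(spec$lengthRange[1L]:spec$lengthRange[2L], n, replace = TRUE)
  if (spec$duplicateStrands && n >= 2L) lens[2L] <- lens[1L]
  names(lens) <- ids
  letters <- lapply(lens, function(L) rep(NA_character_, L))
  usedPos <- lapply(lens, function(L) integer(0))  # 1-based paired positions

  structures <- list(); interactions <- list(); planted <- NULL

  addStructure <- function(s, stem, strength = "strong") {
    keep <- logical(nrow(stem))
    for (r in seq_len(nrow(stem))) {
      upd <- .fillPair(letters[[s]], stem[r, 1L], stem[r, 2L], strength)
      if (!is.null(upd)) { letters[[s]] <<- upd; keep[r] <- TRUE }
    }
    stem <- stem[keep, , drop = FALSE]
    if (nrow(stem) == 0L) return(NULL)
    usedPos[[s]] <<- unique(c(usedPos[[s]], stem[, 1L], stem[, 2L]))
    structureVertex(s, stem - 1L)
  }
  addInteraction <- function(sA, sB, site, strength = "strong") {
    keep <- logical(nrow(site))
    la <- lens[[sA]]
    for (r in seq_len(nrow(site))) {
      combined <- c(letters[[sA]], letters[[sB]])
      upd <- .fillPair(combined, site[r, 1L], la + site[r, 2L], strength)
      if (!is.null(upd)) {
        letters[[sA]] <<- upd[seq_len(la)]
        letters[[sB]] <<- upd[-seq_len(la)]
        keep[r] <- TRUE
      }
    }
    site <- site[keep, , drop = FALSE]
    if (nrow(site) == 0L) return(NULL)
    usedPos[[sA]] <<- unique(c(usedPos[[sA]], site[, 1L]))
    usedPos[[sB]] <<- unique(c(usedPos[[sB]], site[, 2L]))
    interactionVertex(sA, sB, site - 1L)
  }

  if (spec$plantOptimum) {
    # plant: per strand a pure-GC 5-bp stem on positions 2..16; one strong
    # duplex on the free tails of the first feasible strand pair. Decoys
    # are weight-0 candidates; decoy interactions are anchored on planted
    # positions so that nothing weight-0 can extend the plant.
    planted <- list(structures = list(), interactions = list())
    plantedPos <- lapply(lens, function(L) integer(0))
    for (s in ids) {
      stem <- cbind(2L + 0:4, 16L - 0:4)
      v <- addStructure(s, stem, strength = "gc")
      stopifnot(!is.null(v), nrow(v@pairs) == 5L)
      plantedPos[[s]] <- c(stem[, 1L], stem[, 2L])
      planted$structures[[s]] <- v
      structures[[length(structures) + 1L]] <- v
    }
    pairsOf <- utils::combn(ids, 2L)
    for (k in seq_len(ncol(pairsOf))) {
      sA <- pairsOf[1L, k]; sB <- pairsOf[2L, k]
      L <- min(6L, lens[[sA]] - 16L, lens[[sB]] - 16L)
      if (L < 3L) next
      aPos <- (lens[[sA]] - L + 1L) + 0:(L - 1L)
      bPos <- lens[[sB]] - 0:(L - 1L)
      v <- addInteraction(sA, sB, cbind(aPos, bPos), strength = "gc")
      if (is.null(v) || nrow(v@pairs) < L) next
      plantedPos[[sA]] <- c(plantedPos[[sA]], aPos)
      plantedPos[[sB]] <- c(plantedPos[[sB]], bPos)
      planted$interactions[[length(planted$interactions) + 1L]] <- v
      interactions[[length(interactions) + 1L]] <- v
      break   # one strong interaction keeps the plant simple and unique
    }
    stopifnot(length(planted$interactions) >= 1L)
    for (s in ids) {
      for (k in seq_len(max(0L, spec$structuresPerStrand - 1L))) {
        stem <- .placeStem(lens[[s]], 2L, usedPos[[s]], TRUE)
        if (is.null(stem)) next
        v <- addStructure(s, stem, strength = "any")
        if (!is.null(v)) structures[[length(structures) + 1L]] <- v
      }
    }
    for (k in seq_len(ncol(pairsOf))) {
      sA <- pairsOf[1L, k]; sB <- pairsOf[2L, k]
      for (t in seq_len(spec$interactionsPerPair)) {
        pa <- sample(plantedPos[[sA]], 1L)        # force conflict with plant
        pb <- sample(seq_len(lens[[sB]]), 1L)
        v <- addInteraction(sA, sB, cbind(pa, pb), strength = "any")
        if (!is.null(v)) interactions[[length(interactions) + 1L]] <- v
      }
    }
  } else {
    for (s in ids) {
      for (k in seq_len(spec$structuresPerStrand)) {
        ov <- k > 1L && stats::runif(1) < spec$overlapProb
        len <- lens[[s]]
        if (stats::runif(1) < spec$pseudoknotProb && len >= 14L) {
          # two interleaved helices: blocks b1 < b2 < b3 < b4 with
          # b1 pairing b3 and b2 pairing b4 -> crossing pairs
          L <- 3L
          q <- len %/% 4L
          b <- vapply(1:4, function(k0)
            (k0 - 1L) * q + sample.int(max(1L, q - L), 1L), 0L)
          pk <- rbind(cbind(b[1L] + 0:(L - 1L), (b[3L] + L - 1L) - 0:(L - 1L)),
                      cbind(b[2L] + 0:(L - 1L), (b[4L] + L - 1L) - 0:(L - 1L)))
          v <- addStructure(s, pk)
          if (!is.null(v)) structures[[length(structures) + 1L]] <- v
          next
        }
        stem <- .placeStem(len, sample(4:6, 1L), usedPos[[s]], ov)
        if (is.null(stem)) next
        v <- addStructure(s, stem)
        if (!is.null(v)) structures[[length(structures) + 1L]] <- v
      }
    }
    pairsOf <- utils::combn(ids, 2L)
    for (k in seq_len(ncol(pairsOf))) {
      sA <- pairsOf[1L, k]; sB <- pairsOf[2L, k]
      la <- lens[[sA]]; lb <- lens[[sB]]
      for (t in seq_len(spec$interactionsPerPair)) {
        L <- sample(4:6, 1L)
        ov <- stats::runif(1) < spec$overlapProb
        # prefer windows of still-unassigned letters so the duplex keeps
        # its full length after complementary fill-in
        freeA <- which(vapply(seq_len(la - L + 1L), function(i)
          all(is.na(letters[[sA]][i + 0:(L - 1L)])), TRUE))
        freeB <- which(vapply(L:lb, function(j)
          all(is.na(letters[[sB]][j - 0:(L - 1L)])), TRUE)) + L - 1L
        ia <- if (ov && length(usedPos[[sA]])) {
          anch <- if (length(usedPos[[sA]]) == 1L) usedPos[[sA]]
                  else sample(usedPos[[sA]], 1L)
          max(1L, min(anch, la - L + 1L))
        } else if (length(freeA)) {
          if (length(freeA) == 1L) freeA else sample(freeA, 1L)
        } else sample.int(la - L + 1L, 1L)
        ibTop <- if (length(freeB)) {
          if (length(freeB) == 1L) freeB else sample(freeB, 1L)
        } else if (L >= lb) lb else sample(L:lb, 1L)
        site <- cbind(ia + 0:(L - 1L), ibTop - 0:(L - 1L))
        v <- addInteraction(sA, sB, site)
        if (!is.null(v)) interactions[[length(interactions) + 1L]] <- v
      }
    }
  }

  # fill remaining letters at random
  for (s in ids) {
    nas <- is.na(letters[[s]])
    letters[[s]][nas] <- sample(c("A", "C", "G", "U"), sum(nas),
                                replace = TRUE)
  }
  if (spec$duplicateStrands && n >= 2L) {
    # strand 2 becomes a copy of strand 1; its own candidates are dropped
    # and strand 1's are mirrored onto it, so genuinely symmetric
    # complexes occur
    s1 <- ids[1L]; s2 <- ids[2L]
    structures <- structures[vapply(structures,
                                    function(v) v@strand != s2, TRUE)]
    interactions <- interactions[vapply(interactions,
                                        function(v) !s2 %in% v@strands, TRUE)]
    letters[[s2]] <- letters[[s1]]
    for (v in Filter(function(v) v@strand == s1, structures)) {
      p <- v@pairs
      structures[[length(structures) + 1L]] <-
        structureVertex(s2, cbind(p$p1, p$p2))
    }
    for (v in Filter(function(v) s1 %in% v@strands, interactions)) {
      p <- v@pairs
      other <- setdiff(v@strands, s1)
      onS1 <- p$s1 == s1
      mir <- interactionVertex(s2, other,
                               cbind(ifelse(onS1, p$p1, p$p2),
                                     ifelse(onS1, p$p2, p$p1)))
      interactions[[length(interactions) + 1L]] <- mir
    }
  }
  strands <- StrandSet(stats::setNames(
    vapply(letters, paste, "", collapse = ""), ids))
  list(strands = strands, structures = structures,
       interactions = interactions, planted = planted, spec = spec)
}

#' Vertex ids of a planted selection in a built graph
#'
#' @param g graph built from a planted instance
#' @param planted the \code{planted} element of \code{\link{generateInstance}}
#' @return sorted integer vertex ids of the planted clique
#' @export
plantedMembers <- function(g, planted) {
  keys <- vapply(g@vertices, .vertexKey, "")
  want <- vapply(c(planted$structures, planted$interactions), .vertexKey, "")
  m <- match(want, keys)
  if (anyNA(m)) stop("planted vertex not found in graph")
  sort(m)
}

#' Exhaustive constrained-clique optimum
#'
#' Enumerates every selection of one structure vertex per strand crossed
#' with every subset of interaction vertices, keeps the pairwise-compatible
#' non-weak ones, and returns the top \code{topK} by weight. Exact by
#' construction; refuses when the combination count exceeds the guard
#' bound (a silently truncated oracle would be worse than none).
#' Independent of the heuristic solver, which it serves as oracle.
#'
#' @param g a weighted \code{\link{CompatibilityGraph-class}}
#' @param topK how many cliques to return
#' @param guard maximum number of combinations enumerated
#' @return list with \code{members} (list of sorted id vectors),
#'   \code{weight}, \code{energy}, sorted by decreasing weight (ties by
#'   canonical pair-set key)
#' @export
bruteForceOptimum <- function(g, topK = 10L, guard = 2e6) {
  nS <- length(g@strands)
  structIds <- lapply(seq_len(nS), function(s)
    which(g@kind == 0L & g@strandIndex == s))
  inter <- which(g@kind == 1L)
  combs <- prod(lengths(structIds)) * 2^length(inter)
  if (combs > guard)
    stop(sprintf("enumeration would need %.3g combinations (guard bound %.3g)",
                 combs, guard))
  A <- g@adjacency
  w <- graphWeights(g)
  en <- graphEnergies(g)
  members <- list(); weight <- numeric(0); energy <- numeric(0)

  # all pairwise-compatible subsets (incl. empty) among interactions
  interCliques <- list(integer(0))
  for (v in inter) {
    interCliques <- c(interCliques,
                      lapply(Filter(function(cl) all(A[v, cl]),
                                    interCliques), c, v))
  }
  grid <- expand.grid(structIds, KEEP.OUT.ATTRS = FALSE)
  for (r in seq_len(nrow(grid))) {
    sv <- as.integer(grid[r, ])
    if (length(sv) > 1L) {
      sub <- A[sv, sv, drop = FALSE]
      if (!all(sub[upper.tri(sub)])) next
    }
    okInter <- inter[colSums(A[sv, inter, drop = FALSE]) == length(sv)]
    for (cl in interCliques) {
      if (length(cl) && !all(cl %in% okInter)) next
      mem <- c(sv, cl)
      if (sum(g@nPairs[mem]) == 0L) next
      members[[length(members) + 1L]] <- sort(mem)
      weight <- c(weight, sum(w[mem]))
      energy <- c(energy, sum(en[mem]))
    }
  }
  if (length(members)) {
    keys <- vapply(members, function(m)
      .serializePairs(.unionPairs(g, m)), "")
    o <- order(-weight, keys)
    o <- o[seq_len(min(topK, length(o)))]
    members <- members[o]; weight <- weight[o]; energy <- energy[o]
  }
  list(members = members, weight = weight, energy = energy)
}
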
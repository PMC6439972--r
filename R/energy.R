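# Free-energy models: nearest-neighbor (Turner 2004) for pseudoknot-free
# structures and for interactions; stacking-energy sum for pseudoknotted
# structures. Parameters ship as a plain-text resource so energies are
# bit-reproducible across installs.

.paramCache <- new.env(parent = emptyenv())

#' Turner 2004 nearest-neighbor parameters
#'
#' Loads (and caches) the embedded parameter resource: the 6x6 stacking
#' table over canonical pairs (A-U, U-A, G-C, C-G, G-U, U-G), hairpin /
#' bulge / internal-loop length penalties for lengths 1..30 (with the
#' standard logarithmic extrapolation beyond 30), multiloop affine
#' penalties, duplex initiation, terminal AU/GU penalty and the Ninio
#' asymmetry term. All free energies at 37 C in kcal/mol.
#'
#' @return list with elements \code{stack} (named numeric, keys like
#'   \code{"GC/GC"}: outer pair over inner pair, both written 5' to 3' on
#'   the top strand), \code{hairpin}, \code{bulge}, \code{internal}
#'   (numeric length tables) and \code{misc} (named numeric)
#' @export
turnerParams <- function() {
  if (!is.null(.paramCache$turner)) return(.paramCache$turner)
  path <- system.file("extdata", "turner2004_nn.tsv",
                      package = "RNAComplexes", mustWork = TRUE)
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("section", "key", "value"))
  tab$value <- suppressWarnings(as.numeric(tab$value))
  pick <- function(sec) {
    sub <- tab[tab$section == sec, ]
    stats::setNames(sub$value, sub$key)
  }
  lenTable <- function(sec) {
    v <- pick(sec)
    out <- rep(NA_real_, 30L)
    out[as.integer(names(v))] <- v
    out
  }
  p <- list(stack = pick("stack"), hairpin = lenTable("hairpin"),
            bulge = lenTable("bulge"), internal = lenTable("internal"),
            misc = pick("misc"))
  stopifnot(length(p$stack) == 36L)
  .paramCache$turner <- p
  p
}

.canonicalPairs <- c("AU", "UA", "GC", "CG", "GU", "UG")

.checkCanonical <- function(nt1, nt2, where) {
  bad <- !(paste0(nt1, nt2) %in% .canonicalPairs)
  if (any(bad)) {
    k <- which(bad)[1L]
    stop(sprintf("non-canonical base pair %s-%s in %s",
                 nt1[k], nt2[k], where))
  }
}

.stackLookup <- function(params, outer1, outer2, inner1, inner2) {
  params$stack[paste0(outer1, outer2, "/", inner1, inner2)]
}

.loopLen <- function(tab, n, lxc) {
  if (n <= 30L) tab[n] else tab[30L] + lxc * log(n / 30)
}

.terminalAU <- function(params, nt1, nt2) {
  if (paste0(nt1, nt2) %in% c("AU", "UA", "GU", "UG"))
    unname(params$misc["terminal_au"]) else 0
}

# energy of the loop between an outer pair and the next inner pair:
# stack, bulge (stack retained across single-nucleotide bulges) or internal
# loop with Ninio asymmetry. Nucleotides are those of the two pairs.
.twoPairGap <- function(params, n1, n2, o1, o2, i1, i2) {
  misc <- params$misc
  if (n1 == 0L && n2 == 0L)
    return(unname(.stackLookup(params, o1, o2, i1, i2)))
  if (n1 == 0L || n2 == 0L) {
    n <- n1 + n2
    e <- .loopLen(params$bulge, n, misc["loop_extrapolation"])
    if (n == 1L) e <- e + .stackLookup(params, o1, o2, i1, i2)
    else e <- e + .terminalAU(params, o1, o2) + .terminalAU(params, i1, i2)
    return(unname(e))
  }
  e <- .loopLen(params$internal, n1 + n2, misc["loop_extrapolation"]) +
    min(misc["ninio_max"], misc["ninio_m"] * abs(n1 - n2)) +
    .terminalAU(params, o1, o2) + .terminalAU(params, i1, i2)
  unname(e)
}

#' Stacking-energy sum (pseudoknot-capable model)
#'
#' Scores a pair set as the sum of the stacking energies of every stacked
#' adjacency: two pairs whose endpoints are consecutive on both strands
#' (intra- or inter-strand). Isolated pairs contribute nothing; loop terms
#' are not modelled. This is the model used for pseudoknotted structures,
#' where the loop decomposition of the nearest-neighbor model does not
#' apply.
#'
#' @param pairs data.frame of base pairs (columns \code{s1,p1,s2,p2},
#'   0-based, canonical order)
#' @param strands the \code{\link{StrandSet-class}}
#' @param params parameter list from \code{\link{turnerParams}}
#' @return free energy in kcal/mol (0 for empty or fully isolated sets)
#' @export
stackingSumEnergy <- function(pairs, strands, params = turnerParams()) {
  if (nrow(pairs) == 0L) return(0)
  seqs <- strsplit(as.character(strands), "")
  names(seqs) <- names(strands)
  nt <- function(s, p) seqs[[s]][p + 1L]
  a1 <- mapply(nt, pairs$s1, pairs$p1)
  a2 <- mapply(nt, pairs$s2, pairs$p2)
  .checkCanonical(a1, a2, "stacking-sum scoring")
  key <- paste(pairs$s1, pairs$p1, pairs$s2, pairs$p2)
  e <- 0
  for (k in seq_len(nrow(pairs))) {
    innerKey <- paste(pairs$s1[k], pairs$p1[k] + 1L,
                      pairs$s2[k], pairs$p2[k] - 1L)
    m <- match(innerKey, key)
    if (!is.na(m))
      e <- e + .stackLookup(params, a1[k], a2[k], a1[m], a2[m])
  }
  unname(e)
}

#' Nearest-neighbor energy of a pseudoknot-free secondary structure
#'
#' Decomposes the structure into hairpin loops, stacks, bulges, internal
#' loops, multiloops and the exterior loop, and sums the Turner 2004 terms.
#' Terminal AU/GU penalties are applied at helix ends; dangling ends,
#' coaxial stacking and loop terminal-mismatch bonuses are not modelled.
#'
#' @param v a pseudoknot-free \code{StructureVertex}
#' @param strands the \code{\link{StrandSet-class}}
#' @param params parameter list from \code{\link{turnerParams}}
#' @return free energy in kcal/mol; an empty structure scores exactly 0
#' @export
nnStructureEnergy <- function(v, strands, params = turnerParams()) {
  stopifnot(is(v, "StructureVertex"))
  if (v@pseudoknotted)
    stop("pseudoknotted structure: route to stackingSumEnergy()")
  p <- v@pairs
  if (nrow(p) == 0L) return(0)
  seq <- strsplit(as.character(strands[[v@strand]]), "")[[1]]
  i <- p$p1; j <- p$p2
  o <- order(i)
  i <- i[o]; j <- j[o]
  nt <- function(k) seq[k + 1L]
  .checkCanonical(nt(i), nt(j), sprintf("structure on strand %s", v@strand))
  m <- length(i)
  # parent of each pair = tightest enclosing pair (0 = exterior)
  parent <- integer(m)
  for (k in seq_len(m)) {
    enc <- which(i < i[k] & j > j[k])
    parent[k] <- if (length(enc)) enc[which.max(i[enc])] else 0L
  }
  misc <- params$misc
  e <- 0
  # exterior loop: terminal AU per top-level helix
  for (k in which(parent == 0L)) e <- e + .terminalAU(params, nt(i[k]), nt(j[k]))
  for (k in seq_len(m)) {
    ch <- which(parent == k)
    if (length(ch) == 0L) {                       # hairpin loop
      n <- j[k] - i[k] - 1L
      if (n < 3L)
        stop(sprintf("hairpin loop of %d nt between positions %d and %d: physically impossible", n, i[k], j[k]))
      e <- e + .loopLen(params$hairpin, n, misc["loop_extrapolation"]) +
        .terminalAU(params, nt(i[k]), nt(j[k]))
    } else if (length(ch) == 1L) {                # stack / bulge / internal
      kk <- ch[1L]
      e <- e + .twoPairGap(params, i[kk] - i[k] - 1L, j[k] - j[kk] - 1L,
                           nt(i[k]), nt(j[k]), nt(i[kk]), nt(j[kk]))
    } else {                                      # multiloop
      unp <- (j[k] - i[k] - 1L) - sum(j[ch] - i[ch] + 1L)
      e <- e + misc["ml_closing"] + misc["ml_branch"] * (length(ch) + 1L) +
        misc["ml_unpaired"] * unp + .terminalAU(params, nt(i[k]), nt(j[k]))
      for (kk in ch) e <- e + .terminalAU(params, nt(i[kk]), nt(j[kk]))
    }
  }
  unname(e)
}

#' Hybridization energy of an interaction site
#'
#' Scores the site as an RNA-RNA duplex: duplex initiation, stacking terms
#' between consecutive pairs, bulge / internal-loop penalties for gaps
#' between consecutive pairs, and terminal AU/GU penalties at both duplex
#' ends.
#'
#' @param v an \code{InteractionVertex}
#' @param strands the \code{\link{StrandSet-class}}
#' @param params parameter list from \code{\link{turnerParams}}
#' @return free energy in kcal/mol
#' @export
interactionEnergy <- function(v, strands, params = turnerParams()) {
  stopifnot(is(v, "InteractionVertex"))
  p <- v@pairs
  seqs <- strsplit(as.character(strands), "")
  names(seqs) <- names(strands)
  nt <- function(s, pos) seqs[[s]][pos + 1L]
  o <- order(p$p1)
  p <- p[o, , drop = FALSE]
  a <- mapply(nt, p$s1, p$p1)
  b <- mapply(nt, p$s2, p$p2)
  .checkCanonical(a, b, sprintf("interaction %s-%s", v@strands[1], v@strands[2]))
  misc <- params$misc
  m <- nrow(p)
  e <- unname(misc["duplex_init"]) +
    .terminalAU(params, a[1L], b[1L]) + .terminalAU(params, a[m], b[m])
  if (m > 1L) for (k in seq_len(m - 1L)) {
    n1 <- p$p1[k + 1L] - p$p1[k] - 1L
    n2 <- p$p2[k] - p$p2[k + 1L] - 1L
    e <- e + .twoPairGap(params, n1, n2, a[k], b[k], a[k + 1L], b[k + 1L])
  }
  e
}

#' Compute the free energy of every vertex in a graph
#'
#' Routes each vertex to its model: pseudoknot-free structures to the
#' nearest-neighbor model, pseudoknotted structures to the stacking-energy
#' sum, interactions to the duplex model. Empty structures score 0.
#' Energies already present (non-NA) are kept, so candidates arriving with
#' tool-assigned energies pass through untouched.
#'
#' @param g a \code{\link{CompatibilityGraph-class}}
#' @param params parameter list from \code{\link{turnerParams}}
#' @param recompute if TRUE, recompute even non-NA energies
#' @return the graph with all vertex energies set
#' @export
computeVertexEnergies <- function(g, params = turnerParams(),
                                  recompute = FALSE) {
  for (k in seq_along(g@vertices)) {
    v <- g@vertices[[k]]
    if (!is.na(v@energy) && !recompute) next
    v@energy <- if (is(v, "InteractionVertex"))
      interactionEnergy(v, g@strands, params)
    else if (nrow(v@pairs) == 0L) 0
    else if (v@pseudoknotted) stackingSumEnergy(v@pairs, g@strands, params)
    else nnStructureEnergy(v, g@strands, params)
    g@vertices[[k]] <- v
  }
  g
}

#' Assign solver weights from energies
#'
#' The clique search maximizes total weight; setting \code{weight =
#' max(0, -energy)} makes that equivalent to minimizing total free energy
#' over stabilizing candidates, while destabilizing candidates (positive
#' energy) are clamped to 0 and so are never preferred over the empty
#' structure.
#'
#' @param g a \code{\link{CompatibilityGraph-class}} with energies computed
#' @return the graph with all vertex weights set
#' @export
assignWeights <- function(g) {
  for (k in seq_along(g@vertices)) {
    v <- g@vertices[[k]]
    if (is.na(v@energy))
      stop("vertex ", k, " has no energy; run computeVertexEnergies() first")
    v@weight <- max(0, -v@energy)
    g@vertices[[k]] <- v
  }
  g
}
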
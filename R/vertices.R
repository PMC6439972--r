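# Constructors and accessors for candidate vertices.

# canonical pairs data.frame from endpoint vectors
.makePairs <- function(s1, p1, s2, p2) {
  s1 <- as.character(s1); s2 <- as.character(s2)
  p1 <- as.integer(p1);  p2 <- as.integer(p2)
  swap <- s1 > s2 | (s1 == s2 & p1 > p2)
  df <- data.frame(
    s1 = ifelse(swap, s2, s1), p1 = ifelse(swap, p2, p1),
    s2 = ifelse(swap, s1, s2), p2 = ifelse(swap, p1, p2),
    stringsAsFactors = FALSE)
  .sortPairs(df)
}

.sortPairs <- function(df) {
  df <- df[order(df$s1, df$p1, df$s2, df$p2), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.emptyPairs <- function() {
  data.frame(s1 = character(0), p1 = integer(0),
             s2 = character(0), p2 = integer(0), stringsAsFactors = FALSE)
}

# pairs (i, j) with i < j on one strand: crossing iff i < k < j < l
.hasCrossing <- function(i, j) {
  m <- length(i)
  if (m < 2L) return(FALSE)
  for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    lo <- c(i[a], i[b]); hi <- c(j[a], j[b])
    if ((lo[1] < lo[2] & lo[2] < hi[1] & hi[1] < hi[2]) ||
        (lo[2] < lo[1] & lo[1] < hi[2] & hi[2] < hi[1])) return(TRUE)
  }
  FALSE
}

#' Create a candidate secondary-structure vertex
#'
#' @param strand strand id the structure belongs to
#' @param ipairs two-column integer matrix of 0-based paired positions
#'   \code{(i, j)} on that strand; may have zero rows (empty structure)
#' @param energy free energy in kcal/mol, if already known
#' @return a \code{StructureVertex}; \code{pseudoknotted} is derived from
#'   the pair set (crossing pairs present), not from how it was written.
#' @examples
#' structureVertex("A", cbind(c(0L, 1L), c(9L, 8L)))
#' @export
structureVertex <- function(strand, ipairs = NULL, energy = NA_real_) {
  if (is.null(ipairs) || NROW(ipairs) == 0L) {
    pairs <- .emptyPairs()
    pk <- FALSE
  } else {
    ipairs <- matrix(as.integer(ipairs), ncol = 2L)
    pairs <- .makePairs(strand, ipairs[, 1L], strand, ipairs[, 2L])
    pk <- .hasCrossing(pairs$p1, pairs$p2)
  }
  if (nrow(pairs) == 0L && is.na(energy)) energy <- 0
  new("StructureVertex", id = NA_integer_, strand = strand, pairs = pairs,
      pseudoknotted = pk, energy = energy, weight = NA_real_)
}

#' Create a candidate interaction-site vertex
#'
#' @param strand1,strand2 the two distinct strand ids
#' @param ppairs two-column integer matrix: column 1 holds 0-based positions
#'   on \code{strand1}, column 2 the paired positions on \code{strand2}.
#'   The site must be non-crossing (partner positions strictly decreasing),
#'   as produced by duplex-prediction tools; crossing interactions are
#'   represented across vertices, never within one.
#' @param energy free energy in kcal/mol, if already known
#' @return an \code{InteractionVertex}
#' @examples
#' interactionVertex("A", "B", cbind(c(0L, 1L), c(5L, 4L)))
#' @export
interactionVertex <- function(strand1, strand2, ppairs, energy = NA_real_) {
  ppairs <- matrix(as.integer(ppairs), ncol = 2L)
  pairs <- .makePairs(strand1, ppairs[, 1L], strand2, ppairs[, 2L])
  new("InteractionVertex", id = NA_integer_,
      strands = sort(c(strand1, strand2)), pairs = pairs,
      energy = energy, weight = NA_real_)
}

#' @rdname CandidateVertex-class
#' @export
setMethod("vertexPairs", "CandidateVertex", function(x) x@pairs)

#' @rdname CandidateVertex-class
#' @export
setMethod("vertexEnergy", "CandidateVertex", function(x) x@energy)

#' @rdname CandidateVertex-class
#' @export
setMethod("vertexWeight", "CandidateVertex", function(x) x@weight)

#' @rdname CandidateVertex-class
#' @export
setMethod("isEmptyVertex", "CandidateVertex", function(x) nrow(x@pairs) == 0L)

#' @rdname CandidateVertex-class
#' @export
setMethod("isPseudoknotted", "StructureVertex", function(x) x@pseudoknotted)

#' @rdname CandidateVertex-class
#' @export
setMethod("isPseudoknotted", "InteractionVertex", function(x) FALSE)

setMethod("show", "StructureVertex", function(object) {
  cat(sprintf("StructureVertex[%s] strand %s, %d pair(s)%s, energy %s\n",
              ifelse(is.na(object@id), "-", object@id), object@strand,
              nrow(object@pairs),
              if (object@pseudoknotted) " (pseudoknotted)" else "",
              ifelse(is.na(object@energy), "NA",
                     sprintf("%.2f", object@energy))))
})

setMethod("show", "InteractionVertex", function(object) {
  cat(sprintf("InteractionVertex[%s] %s-%s, %d pair(s), energy %s\n",
              ifelse(is.na(object@id), "-", object@id),
              object@strands[1L], object@strands[2L], nrow(object@pairs),
              ifelse(is.na(object@energy), "NA",
                     sprintf("%.2f", object@energy))))
})
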
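#' Construct a StrandSet
#'
#' @param sequences named character vector of RNA sequences (names are the
#'   strand ids). Lowercase letters are folded to uppercase and T to U.
#' @return a \code{\link{StrandSet-class}} object
#' @examples
#' ss <- StrandSet(c(A = "GGAC", B = "GUCC"))
#' strandIDs(ss)
#' @export
StrandSet <- function(sequences) {
  if (is.null(names(sequences)))
    stop("sequences must be named by strand id")
  seqs <- chartr("tT", "uU", sequences)
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad))
    stop(sprintf("strand %s contains characters outside {A,C,G,U,T}",
                 names(sequences)[which(bad)[1L]]))
  new("StrandSet", Biostrings::RNAStringSet(seqs))
}

#' @rdname StrandSet-class
#' @export
setMethod("strandIDs", "StrandSet", function(x) names(x))

#' Read strands from a FASTA file
#'
#' Headers' first whitespace-delimited token becomes the strand id;
#' sequences are normalized (uppercase, T to U) and validated against the
#' {A,C,G,U} alphabet.
#'
#' @param path path to a FASTA file
#' @return a \code{\link{StrandSet-class}}
#' @export
readStrands <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no sequences in ", path)
  ids <- vapply(strsplit(names(raw), "[ \t]+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate strand id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(raw)
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for strand ", ids[which(nchar(seqs) == 0L)[1L]])
  StrandSet(seqs)
}

# cumulative 0-based offsets turning (strand, position) into one integer key
.strandOffsets <- function(strands) {
  w <- Biostrings::width(strands)
  off <- cumsum(c(0L, w[-length(w)]))
  names(off) <- names(strands)
  off
}

.positionKeys <- function(pairs, offsets) {
  if (nrow(pairs) == 0L) return(integer(0))
  c(offsets[pairs$s1] + pairs$p1, offsets[pairs$s2] + pairs$p2)
}

setMethod("show", "StrandSet", function(object) {
  cat(sprintf("StrandSet of %d strand(s): %s\n", length(object),
              paste(sprintf("%s (%d nt)", names(object),
                            Biostrings::width(object)), collapse = ", ")))
})
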
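# File formats: dot-bracket structure candidates, interaction-site TSV,
# ranked-complex reports. Positions are 1-based in every file and 0-based
# in memory; conversion happens only here.

.BRACKETS <- list(c("(", ")"), c("[", "]"), c("{", "}"), c("<", ">"))

#' Parse a dot-bracket string into a structure vertex
#'
#' Each bracket layer \code{()}, \code{[]}, \code{\{\}}, \code{<>} is parsed
#' by its own stack and the layers' pairs are united, so pseudoknots are
#' written with additional layers. Whether the result is pseudoknotted is
#' derived from the pair set, not from the number of layers used.
#'
#' @param db dot-bracket string, same length as the strand
#' @param strand strand id
#' @param strands \code{\link{StrandSet-class}} (for the length check);
#'   optional
#' @return an (unweighted) \code{StructureVertex}
#' @examples
#' parseDotBracket("((...))", "A")
#' parseDotBracket("([)]", "A")   # crossing pairs: pseudoknotted
#' @export
parseDotBracket <- function(db, strand, strands = NULL) {
  if (!is.null(strands)) {
    if (!strand %in% names(strands)) stop("unknown strand id: ", strand)
    if (nchar(db) != Biostrings::width(strands)[match(strand, names(strands))])
      stop(sprintf("dot-bracket length %d does not match strand %s length",
                   nchar(db), strand))
  }
  chars <- strsplit(db, "")[[1]]
  known <- c(".", unlist(.BRACKETS))
  if (any(!chars %in% known))
    stop("unexpected character in dot-bracket string: ",
         chars[which(!chars %in% known)[1L]])
  ii <- integer(0); jj <- integer(0)
  for (layer in .BRACKETS) {
    stack <- integer(0)
    for (k in seq_along(chars)) {
      if (chars[k] == layer[1L]) stack <- c(stack, k)
      else if (chars[k] == layer[2L]) {
        if (length(stack) == 0L)
          stop("unbalanced '", layer[2L], "' at position ", k)
        ii <- c(ii, stack[length(stack)] - 1L); jj <- c(jj, k - 1L)
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack))
      stop("unbalanced '", layer[1L], "' at position ", stack[1L])
  }
  structureVertex(strand, cbind(ii, jj))
}

#' Read per-strand structure candidates
#'
#' Plain-text format, one candidate per line:
#' \code{strand_id <TAB> dotbracket [<TAB> source-tag]}; lines starting
#' with \code{#} are comments.
#'
#' @param path file path
#' @param strands \code{\link{StrandSet-class}} the candidates refer to
#' @return list of (unweighted) \code{StructureVertex}
#' @export
readStructureCandidates <- function(path, strands) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L)
      stop("structure record ", k, " needs at least strand_id<TAB>dotbracket")
    out[[k]] <- tryCatch(parseDotBracket(f[2L], f[1L], strands),
                         error = function(e)
                           stop("structure record ", k, " (strand ", f[1L],
                                "): ", conditionMessage(e), call. = FALSE))
  }
  out
}

#' Read interaction-site candidates
#'
#' Tab-separated records: \code{strand1 <TAB> strand2 <TAB> pairs} where
#' \code{pairs} is a comma-separated list of \code{p1-p2} 1-based position
#' pairs (\code{strand1[p1]} pairs \code{strand2[p2]}). An optional fourth
#' column is a free-text source tag.
#'
#' @param path file path
#' @param strands \code{\link{StrandSet-class}}
#' @return list of (unweighted) \code{InteractionVertex}
#' @export
readInteractionCandidates <- function(path, strands) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  w <- Biostrings::width(strands)
  names(w) <- names(strands)
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("interaction record ", k, ": need strand1<TAB>strand2<TAB>pairs")
    s1 <- f[1L]; s2 <- f[2L]
    if (s1 == s2)
      stop("interaction record ", k, ": strands must differ (got ", s1, " twice)")
    for (s in c(s1, s2)) if (!s %in% names(strands))
      stop("interaction record ", k, ": unknown strand id ", s)
    pp <- strsplit(strsplit(f[3L], ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
    p1 <- as.integer(vapply(pp, `[`, "", 1L))
    p2 <- as.integer(vapply(pp, `[`, "", 2L))
    if (anyNA(p1) || anyNA(p2))
      stop("interaction record ", k, ": malformed pair list ", f[3L])
    if (any(p1 < 1L | p1 > w[s1]) || any(p2 < 1L | p2 > w[s2]))
      stop("interaction record ", k, ": position out of range")
    out[[k]] <- tryCatch(interactionVertex(s1, s2, cbind(p1 - 1L, p2 - 1L)),
                         error = function(e)
                           stop("interaction record ", k, ": ",
                                conditionMessage(e), call. = FALSE))
  }
  out
}

#' Render a complex as a combined dot-bracket string
#'
#' Strands are concatenated (joined by \code{&}) and pairs are assigned
#' greedily to the first bracket layer that accepts them without crossing.
#' Returns NULL when more than four layers would be needed; callers then
#' fall back to the explicit pair list.
#'
#' @param pairs data.frame of base pairs
#' @param strands \code{\link{StrandSet-class}}
#' @return character scalar or NULL
#' @export
renderDotBracket <- function(pairs, strands) {
  off <- .strandOffsets(strands)
  gi <- off[pairs$s1] + pairs$p1
  gj <- off[pairs$s2] + pairs$p2
  o <- order(gi, -gj)
  gi <- gi[o]; gj <- gj[o]
  layerOf <- integer(length(gi))
  for (k in seq_along(gi)) {
    placed <- FALSE
    for (L in seq_along(.BRACKETS)) {
      prev <- which(layerOf[seq_len(k - 1L)] == L)
      crosses <- any((gi[prev] < gi[k] & gi[k] < gj[prev] & gj[prev] < gj[k]) |
                     (gi[k] < gi[prev] & gi[prev] < gj[k] & gj[k] < gj[prev]))
      if (!crosses) { layerOf[k] <- L; placed <- TRUE; break }
    }
    if (!placed) return(NULL)
  }
  w <- Biostrings::width(strands)
  chars <- rep(".", sum(w))
  for (k in seq_along(gi)) {
    chars[gi[k] + 1L] <- .BRACKETS[[layerOf[k]]][1L]
    chars[gj[k] + 1L] <- .BRACKETS[[layerOf[k]]][2L]
  }
  pieces <- character(length(w))
  for (s in seq_along(w))
    pieces[s] <- paste(chars[(off[s] + 1L):(off[s] + w[s])], collapse = "")
  paste(pieces, collapse = "&")
}

.pairString <- function(pairs) {
  if (nrow(pairs) == 0L) return("")
  o <- order(pairs$s1, pairs$p1)
  paste(sprintf("%s:%d-%s:%d", pairs$s1[o], pairs$p1[o] + 1L,
                pairs$s2[o], pairs$p2[o] + 1L), collapse = ",")
}

.parsePairString <- function(str) {
  if (!nzchar(str)) return(.emptyPairs())
  parts <- strsplit(strsplit(str, ",", fixed = TRUE)[[1]], "[:-]")
  .makePairs(vapply(parts, `[`, "", 1L),
             as.integer(vapply(parts, `[`, "", 2L)) - 1L,
             vapply(parts, `[`, "", 3L),
             as.integer(vapply(parts, `[`, "", 4L)) - 1L)
}

#' Write ranked complexes
#'
#' \code{writeComplexes} writes the human-readable report (rank, energy,
#' member provenance, a combined multi-strand dot-bracket rendering where
#' four bracket layers suffice, and the explicit pair list);
#' \code{writePredictionsTSV} writes the machine-readable table
#' (rank, energy, n_pairs, pairs) that \code{readPredictionsTSV} parses
#' back. Output is deterministic for fixed input.
#'
#' @param predictions ranked list of \code{\link{ComplexPrediction-class}}
#' @param path output file
#' @param g the \code{\link{CompatibilityGraph-class}} predictions refer to
#' @export
writeComplexes <- function(predictions, path, g) {
  strands <- g@strands
  lines <- c("# ranked RNA complex predictions",
             sprintf("# strands: %s",
                     paste(sprintf("%s (%d nt)", names(strands),
                                   Biostrings::width(strands)),
                           collapse = ", ")),
             sprintf("# sequences: %s",
                     paste(as.character(strands), collapse = "&")))
  for (p in predictions) {
    lines <- c(lines, sprintf("## rank %d  energy %.2f kcal/mol  %d base pairs",
                              p@rank, p@energy, nrow(p@pairs)))
    for (m in p@members) {
      v <- g@vertices[[m]]
      lines <- c(lines, sprintf("# member %d: %s", m,
        if (is(v, "InteractionVertex"))
          sprintf("interaction %s-%s, %d pairs, %.2f kcal/mol",
                  v@strands[1], v@strands[2], nrow(v@pairs), v@energy)
        else sprintf("structure %s, %d pairs%s, %.2f kcal/mol", v@strand,
                     nrow(v@pairs),
                     if (v@pseudoknotted) " (pseudoknotted)" else "",
                     v@energy)))
    }
    db <- renderDotBracket(p@pairs, strands)
    if (is.null(db))
      lines <- c(lines, "# needs more than 4 bracket layers; pair list only")
    else lines <- c(lines, db)
    lines <- c(lines, paste0("pairs: ", .pairString(p@pairs)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeComplexes
#' @export
writePredictionsTSV <- function(predictions, path) {
  lines <- "rank\tenergy\tn_pairs\tpairs"
  for (p in predictions)
    lines <- c(lines, sprintf("%d\t%.4f\t%d\t%s", p@rank, p@energy,
                              nrow(p@pairs), .pairString(p@pairs)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeComplexes
#' @return \code{readPredictionsTSV}: data.frame with columns rank, energy
#'   and a list-column \code{pairs} of base-pair data.frames
#' @export
readPredictionsTSV <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c("integer", "numeric", "integer",
                                          "character"))
  tab$pairs <- lapply(tab$pairs, .parsePairString)
  tab
}

#' Write a generated instance to disk
#'
#' Writes the three input files of the pipeline (FASTA sequences,
#' dot-bracket structure candidates, interaction TSV) so generated
#' instances double as end-to-end inputs.
#'
#' @param instance list from \code{\link{generateInstance}}
#' @param prefix path prefix; files become \code{<prefix>.fa},
#'   \code{<prefix>_structures.txt}, \code{<prefix>_interactions.tsv}
#' @return named character vector of the three paths
#' @export
writeInstance <- function(instance, prefix) {
  strands <- instance$strands
  fa <- paste0(prefix, ".fa")
  writeLines(as.vector(rbind(paste0(">", names(strands)),
                             as.character(strands))), fa)
  st <- paste0(prefix, "_structures.txt")
  lines <- "# strand_id\tdotbracket"
  for (v in instance$structures) {
    p <- v@pairs
    db <- renderDotBracket(p, strands[v@strand])
    if (is.null(db)) stop("structure candidate needs more than 4 layers")
    lines <- c(lines, paste0(v@strand, "\t", db))
  }
  writeLines(lines, st)
  it <- paste0(prefix, "_interactions.tsv")
  lines <- "# strand1\tstrand2\tpairs"
  for (v in instance$interactions) {
    p <- v@pairs
    o <- order(p$p1)
    lines <- c(lines, sprintf("%s\t%s\t%s", p$s1[1L], p$s2[1L],
      paste(sprintf("%d-%d", p$p1[o] + 1L, p$p2[o] + 1L), collapse = ",")))
  }
  writeLines(lines, it)
  c(fasta = fa, structures = st, interactions = it)
}

#' Write a run manifest
#'
#' Key-value text file recording the resolved configuration, inputs and
#' outputs of a prediction run; re-running with the same inputs and seed
#' reproduces the ranked output exactly.
#'
#' @param path output path
#' @param config a \code{\link{SolverConfig-class}}
#' @param inputs named character vector of input paths
#' @param outputs named character vector of output paths
#' @export
writeManifest <- function(path, config, inputs = character(0),
                          outputs = character(0)) {
  kv <- c(tool = "RNAComplexes",
          version = as.character(utils::packageVersion("RNAComplexes")),
          maxIterations = config@maxIterations, restarts = config@restarts,
          seed = config@seed, maxSolutions = config@maxSolutions,
          lFrac = config@lFrac, T = config@T, alphaS = config@alphaS,
          alphaR = config@alphaR, phi = config@phi, p0 = config@p0,
          stats::setNames(inputs, paste0("input_", names(inputs))),
          stats::setNames(outputs, paste0("output_", names(outputs))),
          timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  writeLines(paste0(names(kv), "=", unname(kv)), path)
  invisible(path)
}
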
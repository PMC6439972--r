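# Base-pair-level scoring of predictions against a reference complex.

#' Confusion counts over base pairs
#'
#' Counts true/false positive/negative base pairs of a predicted complex
#' against a reference. The negative universe is all unordered pairs of
#' nucleotide positions across the whole complex (intra- and inter-strand):
#' \code{TN = N(N-1)/2 - TP - FP - FN} with \code{N} the total nucleotide
#' count. When strands with identical sequences make the labelling
#' arbitrary, both pair sets are first canonicalized under the symmetry
#' classes so a symmetric relabelling is not penalized.
#'
#' @param predicted,reference data.frames of base pairs (columns
#'   \code{s1,p1,s2,p2}, 0-based, canonical order)
#' @param strands the \code{\link{StrandSet-class}} both refer to
#' @param groups symmetry classes (default from \code{strands}); pass
#'   \code{NULL} to skip symmetry canonicalization
#' @return named numeric vector with elements TP, FP, FN, TN, of class
#'   \code{ConfusionCounts}
#' @export
confusionCounts <- function(predicted, reference, strands,
                            groups = symmetryGroups(strands)) {
  checkKnown <- function(pairs) {
    unk <- setdiff(unique(c(pairs$s1, pairs$s2)), names(strands))
    if (length(unk))
      stop("pair references unknown strand: ", paste(unk, collapse = ", "))
  }
  checkKnown(predicted); checkKnown(reference)
  splitKeys <- function(key) if (key == "") character(0)
    else strsplit(key, ";", fixed = TRUE)[[1]]
  if (!is.null(groups)) {
    pk <- splitKeys(canonicalForm(predicted, groups))
    rk <- splitKeys(canonicalForm(reference, groups))
  } else {
    pk <- splitKeys(.serializePairs(predicted))
    rk <- splitKeys(.serializePairs(reference))
  }
  TP <- sum(pk %in% rk)
  FP <- length(pk) - TP
  FN <- length(rk) - TP
  N <- sum(Biostrings::width(strands))
  TN <- N * (N - 1) / 2 - TP - FP - FN
  structure(c(TP = TP, FP = FP, FN = FN, TN = TN),
            class = "ConfusionCounts")
}

.safeRatio <- function(num, den) if (den <= 0) 0 else num / den

#' Base-pair prediction statistics
#'
#' Sensitivity \code{TP/(TP+FN)} (recall), positive predictive value
#' \code{TP/(TP+FP)} (precision), their harmonic mean (F1), and the
#' Matthews correlation coefficient balancing sensitivity and specificity.
#' Zero denominators return 0 by convention so degenerate cases never
#' propagate NaN into aggregated means.
#'
#' @param counts a \code{ConfusionCounts} vector (or any named vector with
#'   TP, FP, FN, TN)
#' @return numeric scalar (fractions in [0,1]; MCC in [-1,1])
#' @export
sensitivity <- function(counts) .safeRatio(counts[["TP"]],
                                           counts[["TP"]] + counts[["FN"]])

#' @rdname sensitivity
#' @export
ppv <- function(counts) .safeRatio(counts[["TP"]],
                                   counts[["TP"]] + counts[["FP"]])

#' @rdname sensitivity
#' @export
f1score <- function(counts) {
  s <- sensitivity(counts); p <- ppv(counts)
  .safeRatio(2 * s * p, s + p)
}

#' @rdname sensitivity
#' @export
mcc <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  fn <- counts[["FN"]]; tn <- counts[["TN"]]
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den <= 0) 0 else (tp * tn - fp * fn) / den
}

#' Score a ranked prediction list against a reference
#'
#' Computes the four statistics for every returned rank and summarizes the
#' best F1 over the top-k ranks (the headline summary when the true
#' complex is expected among the near-optimal solutions rather than
#' strictly at rank 1).
#'
#' @param predictions list of \code{\link{ComplexPrediction-class}}
#' @param reference data.frame of reference base pairs
#' @param strands the \code{\link{StrandSet-class}}
#' @param topK ranks considered for the best-over-top-k summary
#' @return list with \code{perRank} (data.frame: rank, energy, TP, FP, FN,
#'   TN, sens, ppv, f1, mcc), \code{bestF1} and \code{bestF1Rank}
#' @export
evaluateRun <- function(predictions, reference, strands, topK = 10L) {
  stopifnot(length(predictions) >= 1L)
  rows <- lapply(predictions, function(p) {
    cc <- confusionCounts(p@pairs, reference, strands)
    data.frame(rank = p@rank, energy = p@energy,
               TP = cc[["TP"]], FP = cc[["FP"]], FN = cc[["FN"]],
               TN = cc[["TN"]], sens = sensitivity(cc), ppv = ppv(cc),
               f1 = f1score(cc), mcc = mcc(cc))
  })
  perRank <- do.call(rbind, rows)
  top <- perRank[perRank$rank <= topK, , drop = FALSE]
  best <- which.max(top$f1)
  list(perRank = perRank, bestF1 = top$f1[best],
       bestF1Rank = top$rank[best])
}
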
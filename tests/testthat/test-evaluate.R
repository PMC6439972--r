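test_that("statistics reproduce hand-derived values", {
  # worked example computed directly from the defining formulas
  cc <- structure(c(TP = 6, FP = 2, FN = 3, TN = 9), class = "ConfusionCounts")
  expect_equal(sensitivity(cc), 0.6667, tolerance = 1e-4)
  expect_equal(ppv(cc), 0.75, tolerance = 1e-4)
  expect_equal(f1score(cc), 0.7059, tolerance = 1e-4)
  expect_equal(mcc(cc), 0.4924, tolerance = 1e-4)

  perfect <- c(TP = 10, FP = 0, FN = 0, TN = 90)
  expect_equal(c(sensitivity(perfect), ppv(perfect), f1score(perfect),
               mcc(perfect)), c(1, 1, 1, 1))
  balanced <- c(TP = 1, FP = 1, FN = 1, TN = 1)
  expect_identical(mcc(balanced), 0)
  # zero-denominator conventions
  nothing <- c(TP = 0, FP = 0, FN = 0, TN = 10)
  expect_identical(c(sensitivity(nothing), ppv(nothing), f1score(nothing),
                     mcc(nothing)), c(0, 0, 0, 0))
})

test_that("statistics stay in range and F1 collapses when FP equals FN", {
  set.seed(7)
  for (rep in 1:200) {
    cc <- c(TP = sample(0:20, 1), FP = sample(0:20, 1),
            FN = sample(0:20, 1), TN = sample(0:50, 1))
    s <- sensitivity(cc); p <- ppv(cc); f <- f1score(cc); m <- mcc(cc)
    expect_true(s >= 0 && s <= 1 && p >= 0 && p <= 1 && f >= 0 && f <= 1)
    expect_true(m >= -1 && m <= 1)
    if (cc[["FP"]] == cc[["FN"]] && cc[["TP"]] > 0) {
      expect_equal(f, s)
      expect_equal(f, p)
    }
  }
})

test_that("confusion counts match exhaustive membership counting", {
  ss <- StrandSet(c(A = "GGGGG", B = "CCCCC"))
  set.seed(11)
  allPos <- expand.grid(s = c("A", "B"), p = 0:4, stringsAsFactors = FALSE)
  randomSet <- function(n) {
    rows <- list()
    used <- character(0)
    while (length(rows) < n) {
      k <- sample(nrow(allPos), 2L)
      a <- allPos[k[1L], ]; b <- allPos[k[2L], ]
      ka <- paste(a$s, a$p); kb <- paste(b$s, b$p)
      if (ka == kb || ka %in% used || kb %in% used) next
      used <- c(used, ka, kb)
      rows[[length(rows) + 1L]] <- RNAComplexes:::.makePairs(a$s, a$p, b$s, b$p)
    }
    do.call(rbind, c(rows, list(RNAComplexes:::.emptyPairs())))
  }
  for (rep in 1:20) {
    pred <- randomSet(sample(0:4, 1L))
    ref <- randomSet(sample(0:4, 1L))
    cc <- confusionCounts(pred, ref, ss, groups = NULL)
    # oracle: classify every unordered position pair of the universe
    pk <- RNAComplexes:::.serializePairs(pred)
    rk <- RNAComplexes:::.serializePairs(ref)
    pk <- if (pk == "") character(0) else strsplit(pk, ";")[[1]]
    rk <- if (rk == "") character(0) else strsplit(rk, ";")[[1]]
    uni <- utils::combn(paste(allPos$s, allPos$p), 2L)
    tally <- c(TP = 0, FP = 0, FN = 0, TN = 0)
    for (c1 in seq_len(ncol(uni))) {
      x <- strsplit(uni[, c1], " ")
      key <- RNAComplexes:::.serializePairs(RNAComplexes:::.makePairs(
        x[[1]][1], as.integer(x[[1]][2]), x[[2]][1], as.integer(x[[2]][2])))
      inP <- key %in% pk; inR <- key %in% rk
      slot <- if (inP && inR) "TP" else if (inP) "FP"
              else if (inR) "FN" else "TN"
      tally[slot] <- tally[slot] + 1
    }
    expect_identical(unclass(cc)[names(tally)], tally)
  }
})

test_that("counts are invariant under within-class relabelling of both sets", {
  ss <- StrandSet(c(A = "GGGGG", B = "GGGGG", C = "CCCCC"))
  pred <- vertexPairs(interactionVertex("A", "C", cbind(0:1, 4:3)))
  ref <- vertexPairs(interactionVertex("B", "C", cbind(0:1, 4:3)))
  cc <- confusionCounts(pred, ref, ss)
  expect_identical(cc[["TP"]], 2)
  expect_identical(cc[["FP"]], 0)
  map <- c(A = "B", B = "A", C = "C")
  cc2 <- confusionCounts(RNAComplexes:::.relabelPairs(pred, map), ref, ss)
  expect_identical(unclass(cc), unclass(cc2))
  expect_error(confusionCounts(
    vertexPairs(interactionVertex("A", "Z", cbind(0L, 1L))), ref, ss),
    "unknown strand")
})

test_that("evaluateRun reports per-rank statistics and best-over-top-k", {
  inst <- twoStrandFixture()
  g <- builtGraph(inst)
  preds <- dedupAndRank(solveComplexes(g, solverConfig(seed = 3)), g)
  ref <- preds[[1L]]@pairs
  res <- evaluateRun(preds, ref, g@strands)
  expect_identical(colnames(res$perRank),
                   c("rank", "energy", "TP", "FP", "FN", "TN",
                     "sens", "ppv", "f1", "mcc"))
  expect_identical(res$perRank$f1[1L], 1)
  expect_identical(res$bestF1, 1)
  expect_gte(res$bestF1, max(res$perRank$f1[1L]))
  # empty prediction against a non-empty reference: sensitivity 0
  cc <- confusionCounts(RNAComplexes:::.emptyPairs(), ref, g@strands)
  expect_identical(sensitivity(cc), 0)
  expect_identical(cc[["FN"]], nrow(ref) + 0)
})
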
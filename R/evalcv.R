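## Evaluation protocols: pair-level k-fold cross-validation, cold-start
## (novel) disease holdout, ranking metrics and top-k recovery.
## Per fold the evaluation universe is the test positives plus all
## never-positive pairs; training positives are never scored.

#' Pair-level k-fold split of the association matrix
#'
#' Positive pairs are shuffled under the seed and partitioned into k
#' near-equal folds. For each fold the training adjacency keeps all positives
#' except the fold; every never-positive pair is a test negative; the
#' training negative set is all never-positive pairs by default, or a
#' per-fold subsample of `negRatio` negatives per training positive.
#' `positiveFraction < 1` removes a random share of positives from the
#' experiment entirely (they are neither trained on nor scored).
#'
#' @param assoc an \linkS4class{AssociationMatrix} or binary matrix.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @param negRatio optional negatives-per-positive training subsample ratio.
#' @param positiveFraction fraction of positives retained (default 1).
#' @return list of fold splits; each has `foldId`, `trainPositive`,
#'   `testPositive`, `trainNegative` (NULL = all never-positives),
#'   `droppedPositive`.
#' @export
kfoldPairSplit <- function(assoc, k, seed = 1, negRatio = NULL,
                           positiveFraction = 1) {
  A <- if (is(assoc, "AssociationMatrix")) assoc@adj else assoc
  if (k < 2) stop("k must be >= 2")
  pos <- which(A == 1, arr.ind = TRUE)
  set.seed(seed)
  dropped <- NULL
  if (positiveFraction < 1) {
    keepN <- round(positiveFraction * nrow(pos))
    keep <- sort(sample.int(nrow(pos), keepN))
    dropped <- pos[-keep, , drop = FALSE]
    pos <- pos[keep, , drop = FALSE]
  }
  if (nrow(pos) < k) stop("fewer positives than folds")
  foldId <- sample(rep_len(seq_len(k), nrow(pos)))   # balanced fold sizes
  neg <- which(A == 0, arr.ind = TRUE)
  lapply(seq_len(k), function(f) {
    trainPos <- pos[foldId != f, , drop = FALSE]
    testPos <- pos[foldId == f, , drop = FALSE]
    trainNeg <- NULL
    if (!is.null(negRatio)) {
      nneg <- min(nrow(neg), round(negRatio * nrow(trainPos)))
      trainNeg <- neg[sample.int(nrow(neg), nneg), , drop = FALSE]
    }
    list(foldId = f, trainPositive = trainPos, testPositive = testPos,
         trainNegative = trainNeg, droppedPositive = dropped)
  })
}

#' Cold-start disease holdout split
#'
#' Holds out a random fraction of disease columns; all their positives become
#' test positives and are removed from the training adjacency (the held-out
#' columns are all-zero in training), the remaining pairs in held-out columns
#' are test negatives. If a draw yields zero test positives it is redrawn
#' once, then an error is raised. With `mode = "partition"` the five repeats
#' driven by `seed`, `seed + 1`, ... cover disjoint 20% blocks.
#'
#' @param assoc an \linkS4class{AssociationMatrix} or binary matrix.
#' @param fraction fraction of diseases held out (0 < fraction < 1).
#' @param seed integer seed.
#' @param mode `"independent"` random draws (default) or `"partition"`
#'   (seed selects a block of a seed-determined disjoint partition).
#' @return fold split list with `heldDiseases`, `trainPositive`,
#'   `testPositive`.
#' @export
novelDiseaseSplit <- function(assoc, fraction, seed = 1,
                              mode = c("independent", "partition")) {
  A <- if (is(assoc, "AssociationMatrix")) assoc@adj else assoc
  mode <- match.arg(mode)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  N <- ncol(A)
  nHold <- max(1L, round(fraction * N))
  draw <- function(s) {
    if (mode == "independent") {
      set.seed(s)
      sort(sample.int(N, nHold))
    } else {
      blocks <- ceiling(1 / fraction)
      block <- (s - 1) %% blocks
      set.seed(s - block)              # same base permutation across the cycle
      perm <- sample.int(N)
      idx <- seq.int(block * nHold + 1, min((block + 1) * nHold, N))
      sort(perm[idx])
    }
  }
  held <- draw(seed)
  if (sum(A[, held]) == 0) {
    held <- draw(seed + 977L)
    if (sum(A[, held]) == 0) stop("held-out diseases have no positives")
  }
  pos <- which(A == 1, arr.ind = TRUE)
  inHold <- pos[, 2] %in% held
  list(foldId = seed, heldDiseases = held,
       trainPositive = pos[!inHold, , drop = FALSE],
       testPositive = pos[inHold, , drop = FALSE],
       trainNegative = NULL, droppedPositive = NULL)
}

#' Training adjacency and loss mask implied by a split
#'
#' The training adjacency zeroes all test positives (and dropped positives).
#' The loss mask excludes test positives, dropped positives, every pair of a
#' held-out disease column (cold-start splits), and — when the split carries
#' a negative subsample — all unsampled negatives.
#'
#' @param split a split from [kfoldPairSplit()] or [novelDiseaseSplit()].
#' @param A the full binary association matrix.
#' @return list with `trainA` and `lossMask` matrices.
#' @export
splitTrainingData <- function(split, A) {
  trainA <- matrix(0, nrow(A), ncol(A))
  trainA[split$trainPositive] <- 1
  lossMask <- matrix(1, nrow(A), ncol(A))
  lossMask[split$testPositive] <- 0
  if (!is.null(split$droppedPositive)) lossMask[split$droppedPositive] <- 0
  if (!is.null(split$heldDiseases)) lossMask[, split$heldDiseases] <- 0
  if (!is.null(split$trainNegative)) {
    negMask <- matrix(0, nrow(A), ncol(A))
    negMask[split$trainNegative] <- 1
    negMask[split$trainPositive] <- 1
    lossMask <- lossMask * negMask
  }
  list(trainA = trainA, lossMask = lossMask)
}

#' Evaluation pairs of a split
#'
#' Test positives plus all never-positive pairs (training positives excluded
#' from scoring); for cold-start splits the universe is restricted to the
#' held-out disease columns.
#'
#' @param split a fold split.
#' @param A the full binary association matrix.
#' @return list with `pairs` (index matrix) and `labels` (0/1 vector).
#' @export
evaluationPairs <- function(split, A) {
  if (!is.null(split$heldDiseases)) {
    sub <- A[, split$heldDiseases, drop = FALSE]
    pr <- which(sub >= 0, arr.ind = TRUE)
    pairs <- cbind(pr[, 1], split$heldDiseases[pr[, 2]])
    labels <- as.integer(A[pairs] == 1)
  } else {
    neg <- which(A == 0, arr.ind = TRUE)
    pairs <- rbind(split$testPositive, neg)
    labels <- c(rep(1L, nrow(split$testPositive)), rep(0L, nrow(neg)))
  }
  list(pairs = pairs, labels = labels)
}

#' Ranking and threshold metrics
#'
#' AUROC by the rank statistic (ties averaged), AUPR by non-interpolated
#' precision-recall step integration, plus recall, accuracy and F1 at the
#' given score threshold.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 label vector (both classes required).
#' @param threshold classification threshold (default 0.5).
#' @return named list: `auroc`, `aupr`, `recall`, `accuracy`, `f1`.
#' @export
computeMetrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(-scores, seq_along(scores))
  tp <- cumsum(labels[ord] == 1)
  prec <- tp / seq_along(tp)
  rec <- tp / np
  aupr <- sum(diff(c(0, rec)) * prec)
  pred <- as.integer(scores >= threshold)
  tpos <- sum(pred == 1 & labels == 1)
  recall <- tpos / np
  accuracy <- mean(pred == labels)
  precision <- if (sum(pred == 1) == 0) 0 else tpos / sum(pred == 1)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(auroc = auroc, aupr = aupr, recall = recall, accuracy = accuracy,
       f1 = f1)
}

#' Positives recovered among the top-k scored test pairs
#'
#' @param scores numeric score vector over the evaluation pairs.
#' @param labels 0/1 labels aligned with `scores`.
#' @param k size of the candidate list (1 <= k <= length(scores)); boundary
#'   ties broken by input order.
#' @return integer count of recovered positives.
#' @export
topkRecovery <- function(scores, labels, k) {
  if (k <= 0) stop("k must be positive")
  if (k > length(scores)) stop("k exceeds the number of scored pairs")
  ord <- order(-scores, seq_along(scores))
  sum(as.integer(labels[ord[seq_len(k)]]) == 1)
}

.assertNoLeakage <- function(split, trainA) {
  if (any(trainA[split$testPositive] != 0))
    stop("leakage: a test positive is present in the training adjacency")
  invisible(TRUE)
}

#' Cross-validated evaluation of the model
#'
#' Trains a fresh model per fold (or repeat) on the masked adjacency, scores
#' the fold's evaluation pairs, and aggregates the metric suite as mean and
#' standard deviation. Fold-level leakage (a test positive present in a
#' training adjacency) is asserted programmatically on every split.
#'
#' @param network a \linkS4class{HeteroNetwork}.
#' @param cfg a [modelConfig()]; fold f trains with seed `cfg$seed + f`.
#' @param protocol `"kfold"` pair-level CV or `"novel"` cold-start disease
#'   holdout.
#' @param folds number of folds (kfold).
#' @param repeats number of repeats (novel).
#' @param fraction held-out disease fraction (novel, default 0.2).
#' @param seed split seed (repeat r uses `seed + r - 1`).
#' @param negRatio optional training negative subsample ratio (kfold).
#' @param positiveFraction fraction of positives retained (kfold).
#' @param threshold score threshold for recall/accuracy/F1.
#' @param topk optional k for top-k recovery per fold.
#' @param verbose print per-fold metrics.
#' @return list of class `evalReport` with `perFold` (data.frame), `mean`,
#'   `sd`, and the echoed configuration.
#' @export
crossValidate <- function(network, cfg, protocol = c("kfold", "novel"),
                          folds = 10, repeats = 5, fraction = 0.2, seed = 1,
                          negRatio = NULL, positiveFraction = 1,
                          threshold = 0.5, topk = NULL, verbose = FALSE) {
  protocol <- match.arg(protocol)
  A <- network@assoc@adj
  splits <- if (protocol == "kfold") {
    kfoldPairSplit(network@assoc, folds, seed, negRatio, positiveFraction)
  } else {
    lapply(seq_len(repeats), function(r)
      novelDiseaseSplit(network@assoc, fraction, seed + r - 1))
  }
  rows <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    td <- splitTrainingData(sp, A)
    .assertNoLeakage(sp, td$trainA)
    trainNet <- network
    trainNet@assoc <- AssociationMatrix(drugIds(network), diseaseIds(network),
                                        td$trainA)
    cfgFold <- cfg
    cfgFold$seed <- cfg$seed + i
    fit <- trainModel(trainNet, cfgFold, lossMask = td$lossMask)
    scores <- predictScores(trainNet, fit)
    ev <- evaluationPairs(sp, A)
    met <- computeMetrics(scores[ev$pairs], ev$labels, threshold)
    row <- data.frame(fold = i, auroc = met$auroc, aupr = met$aupr,
                      recall = met$recall, accuracy = met$accuracy,
                      f1 = met$f1,
                      finalLoss = fit$log$loss[nrow(fit$log)])
    if (!is.null(topk))
      row$topk <- topkRecovery(scores[ev$pairs], ev$labels, topk)
    rows[[i]] <- row
    if (verbose)
      message(sprintf("fold %d: AUROC %.3f AUPR %.3f", i, met$auroc, met$aupr))
  }
  perFold <- do.call(rbind, rows)
  metCols <- setdiff(names(perFold), "fold")
  structure(list(perFold = perFold,
                 mean = colMeans(perFold[metCols]),
                 sd = vapply(perFold[metCols], stats::sd, numeric(1)),
                 protocol = protocol, folds = length(splits),
                 threshold = threshold, cfg = cfg, seed = seed),
            class = "evalReport")
}

#' @export
print.evalReport <- function(x, ...) {
  cat(sprintf("Cross-validation report (%s, %d fold(s))\n", x$protocol, x$folds))
  for (m in c("auroc", "aupr", "recall", "accuracy", "f1"))
    cat(sprintf("  %-9s %.4f +/- %.4f\n", toupper(m), x$mean[[m]], x$sd[[m]]))
  invisible(x)
}
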
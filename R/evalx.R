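## Evaluation: confusion matrices, the printed one-vs-rest metric formulas,
## hierarchical 7 -> 3 -> 2 class collapsing, rank-based ROC AUC, latent
## export. Confusion matrices are plain integer matrices (rows = actual,
## columns = predicted) carrying their class order in dimnames.

#' Confusion matrix from label sequences
#'
#' @param trueLabels,predLabels equal-length label vectors (character labels
#'   or 0-based integer codes).
#' @param classes class order; defaults to [aoClasses()] for character
#'   input, or `0:(K-1)` labels for integer input with `K = max + 1`.
#' @return K x K integer matrix, rows = actual, columns = predicted.
#' @export
confusionMatrix <- function(trueLabels, predLabels, classes = NULL) {
  if (!length(trueLabels)) stop("empty label input")
  if (length(trueLabels) != length(predLabels))
    stop("label sequences must have equal length")
  if (is.numeric(trueLabels)) {
    K <- if (is.null(classes)) max(trueLabels, predLabels) + 1L
         else length(classes)
    if (is.null(classes)) classes <- as.character(seq_len(K) - 1L)
    if (any(trueLabels < 0 | trueLabels >= K | predLabels < 0 |
            predLabels >= K))
      stop("label out of range")
    trueLabels <- classes[trueLabels + 1L]
    predLabels <- classes[predLabels + 1L]
  } else if (is.null(classes)) {
    classes <- aoClasses()
  }
  if (!all(trueLabels %in% classes) || !all(predLabels %in% classes))
    stop("label out of range")
  tf <- factor(trueLabels, levels = classes)
  pf <- factor(predLabels, levels = classes)
  m <- table(actual = tf, predicted = pf)
  matrix(as.integer(m), nrow = length(classes),
         dimnames = list(actual = classes, predicted = classes))
}

#' One-vs-rest counts for a class
#'
#' TP is the diagonal entry; FP the rest of the class column; FN the rest of
#' the class row; TN the remainder.
#'
#' @param cm confusion matrix (rows = actual, columns = predicted).
#' @param class class name or index.
#' @return named vector `c(TP, FP, FN, TN)`.
#' @export
perClassCounts <- function(cm, class) {
  i <- if (is.character(class)) match(class, rownames(cm)) else class
  if (is.na(i) || i < 1 || i > nrow(cm)) stop("invalid class")
  TP <- cm[i, i]
  FP <- sum(cm[, i]) - TP
  FN <- sum(cm[i, ]) - TP
  TN <- sum(cm) - TP - FP - FN
  c(TP = TP, FP = FP, FN = FN, TN = TN)
}

#' Classification metrics from a confusion matrix
#'
#' Per class, one-vs-rest: accuracy = (TP+TN)/(TP+TN+FP+FN), precision =
#' TP/(TP+FP), recall = TP/(TP+FN), F1 = 2*precision*recall/(precision+
#' recall). Overall accuracy is trace/total; the average F1 is the
#' unweighted (macro) mean of per-class F1. A ratio with zero denominator is
#' reported as 0 and flagged in the `undefined` column (this happens for
#' classes never predicted, e.g. very rare ones).
#'
#' @param cm confusion matrix (rows = actual, columns = predicted).
#' @return list with `accuracy`, `macroF1`, and `perClass` data.frame
#'   (class, TP, FP, FN, TN, precision, recall, F1, undefined).
#' @export
classMetrics <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  classes <- rownames(cm)
  safe <- function(num, den) if (den == 0) c(0, TRUE) else c(num / den, FALSE)
  per <- lapply(seq_along(classes), function(i) {
    ct <- perClassCounts(cm, i)
    pr <- safe(ct["TP"], ct["TP"] + ct["FP"])
    rc <- safe(ct["TP"], ct["TP"] + ct["FN"])
    f1 <- safe(2 * pr[1] * rc[1], pr[1] + rc[1])
    data.frame(class = classes[i], TP = ct["TP"], FP = ct["FP"],
               FN = ct["FN"], TN = ct["TN"],
               accuracy = (ct["TP"] + ct["TN"]) / sum(ct),
               precision = pr[1], recall = rc[1], F1 = f1[1],
               undefined = as.logical(pr[2] | rc[2] | f1[2]),
               row.names = NULL)
  })
  per <- do.call(rbind, per)
  list(accuracy = sum(diag(cm)) / sum(cm),
       macroF1 = mean(per$F1),
       perClass = per)
}

#' The AO/OTA label hierarchy
#'
#' Fine (7-class) to mid (3-class: normal / A trochanteric / B neck) to
#' coarse (2-class: normal / fracture) label maps.
#'
#' @return list of named character vectors `fineToMid` and `midToCoarse`.
#' @export
hierarchyMap <- function() {
  list(fineToMid = c(normal = "normal", A1 = "A", A2 = "A", A3 = "A",
                     B1 = "B", B2 = "B", B3 = "B"),
       midToCoarse = c(normal = "normal", A = "fracture", B = "fracture"))
}

#' Collapse a confusion matrix down the label hierarchy
#'
#' Sums fine-level counts over the label groups; totals are conserved and
#' collapsing 7 -> 3 -> 2 equals collapsing 7 -> 2 directly.
#'
#' @param cm confusion matrix whose row/column names are covered by `map`.
#' @param map named character vector fine label -> coarse label (e.g. the
#'   elements of [hierarchyMap()]).
#' @return collapsed confusion matrix in the order of first appearance of
#'   the coarse labels.
#' @export
collapseConfusion <- function(cm, map) {
  fine <- rownames(cm)
  if (!all(fine %in% names(map))) stop("unmapped label in confusion matrix")
  coarse <- unique(unname(map[fine]))
  out <- matrix(0L, length(coarse), length(coarse),
                dimnames = list(actual = coarse, predicted = coarse))
  for (i in fine) for (j in fine)
    out[map[[i]], map[[j]]] <- out[map[[i]], map[[j]]] + cm[i, j]
  out
}

#' Collapse to a named hierarchy level
#'
#' @param cm a 7-class confusion matrix in [aoClasses()] order.
#' @param level 7 (identity), 3 (normal/A/B) or 2 (normal/fracture).
#' @return confusion matrix at the requested level.
#' @export
collapseToLevel <- function(cm, level) {
  hm <- hierarchyMap()
  switch(as.character(level),
         "7" = cm,
         "3" = collapseConfusion(cm, hm$fineToMid),
         "2" = collapseConfusion(collapseConfusion(cm, hm$fineToMid),
                                 hm$midToCoarse),
         stop("level must be 2, 3 or 7"))
}

#' One-vs-rest ROC AUC
#'
#' Rank-based AUC: the probability that a uniformly random positive outscores
#' a uniformly random negative, with ties counting one half (equivalently
#' the normalized Mann-Whitney U statistic).
#'
#' @param labels binary vector (1/TRUE = positive).
#' @param scores numeric scores, higher = more positive.
#' @return AUC in \[0,1\]; `NA` with a warning if only one class is present.
#' @export
rocAuc <- function(labels, scores) {
  pos <- as.logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-class one-vs-rest AUC from softmax scores
#'
#' @param trueLabels character labels.
#' @param probMatrix n x K matrix of class probabilities, columns in
#'   `classes` order.
#' @param classes class order (default [aoClasses()]).
#' @return named numeric vector of per-class AUCs (NA where a class is
#'   absent).
#' @export
multiclassAuc <- function(trueLabels, probMatrix, classes = aoClasses()) {
  vapply(seq_along(classes), function(i) {
    y <- trueLabels == classes[i]
    if (!any(y) || all(y)) return(NA_real_)
    rocAuc(y, probMatrix[, i])
  }, numeric(1)) |> setNames(classes)
}

#' Evaluate a trained model on a manifest split
#'
#' @param model a trained [FractureNet-class].
#' @param manifest a [DatasetManifest-class].
#' @param split split tag (default `"test"`).
#' @param level hierarchy level 2, 3 or 7 (default 7).
#' @return list with the level confusion matrix `cm`, [classMetrics()]
#'   `metrics`, predicted labels and softmax `probs`.
#' @export
evaluateModel <- function(model, manifest, split = "test", level = 7) {
  ev <- loadSplit(manifest, split, model@configs$encoder$inputSize)
  if (!nrow(ev$rec)) stop(sprintf("no records in split '%s'", split))
  z <- latentCodes(model, ev$images)
  probs <- softmaxRows(classifierForwardCore(model@params, z)$logits)
  pred <- aoClasses()[max.col(probs)]
  cm7 <- confusionMatrix(ev$rec$label, pred)
  cm <- collapseToLevel(cm7, level)
  list(cm = cm, metrics = classMetrics(cm), pred = pred, probs = probs,
       labels = ev$rec$label)
}

#' Export latent codes for a manifest split
#'
#' One row per sample: id, label and the latent dimensions. Deterministic
#' (eval-mode encoder); intended for external 2-D embedding/visualization.
#'
#' @inheritParams evaluateModel
#' @param path optional path to write a tab-delimited table.
#' @return data.frame with columns id, label, z1..zD.
#' @export
exportLatents <- function(model, manifest, split = "test", path = NULL) {
  if (!length(model@params)) stop("model has no trained parameters")
  ev <- loadSplit(manifest, split, model@configs$encoder$inputSize)
  z <- latentCodes(model, ev$images)
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  out <- cbind(data.frame(id = ev$rec$id, label = ev$rec$label,
                          stringsAsFactors = FALSE), as.data.frame(z))
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
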
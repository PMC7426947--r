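# brute-force references (independent loops, no shared code)
bruteMetrics <- function(cm) {
  K <- nrow(cm); tot <- sum(cm)
  out <- list(accuracy = sum(diag(cm)) / tot, f1 = numeric(K),
              prec = numeric(K), rec = numeric(K))
  for (c in 1:K) {
    tp <- cm[c, c]; fp <- sum(cm[, c]) - tp; fn <- sum(cm[c, ]) - tp
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    out$prec[c] <- p; out$rec[c] <- r
    out$f1[c] <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  }
  out
}
bruteAuc <- function(lab, sc) {
  pos <- which(lab == 1); neg <- which(lab == 0)
  s <- 0
  for (i in pos) for (j in neg)
    s <- s + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
  s / (length(pos) * length(neg))
}

test_that("confusion matrices count actual x predicted pairs", {
  cm <- confusionMatrix(c(0, 0, 1), c(0, 1, 1), classes = c("n", "f"))
  expect_equal(unname(cm), matrix(c(1, 0, 1, 1), 2))
  expect_error(confusionMatrix(integer(), integer()), "empty")
  expect_error(confusionMatrix(c(0, 5), c(0, 1), classes = c("a", "b")),
               "out of range")
  # perfect predictions give a diagonal matrix with class counts
  labs <- sample(aoClasses(), 30, TRUE)
  cmP <- confusionMatrix(labs, labs)
  expect_equal(diag(cmP), as.vector(table(factor(labs, aoClasses()))),
               ignore_attr = TRUE)
  expect_true(all(cmP[upper.tri(cmP) | lower.tri(cmP)] == 0))
})

test_that("per-class one-vs-rest counts decompose the matrix total", {
  cm <- matrix(c(5, 2, 1, 4), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  ct <- perClassCounts(cm, "a")
  expect_equal(unname(ct), c(5, 1, 2, 4))
  for (c in 1:2)
    expect_equal(sum(perClassCounts(cm, c)), sum(cm))
})

test_that("metric formulas match brute force on random confusion matrices", {
  m <- classMetrics(matrix(c(3, 2, 1, 4), 2, byrow = TRUE,
                           dimnames = list(c("x", "y"), c("x", "y"))))
  # class x: TP=3 FP=1 FN=2 -> precision .75, recall .6, F1 ~ .6667
  expect_equal(m$perClass$precision[1], 0.75, tolerance = 1e-9)
  expect_equal(m$perClass$recall[1], 0.6, tolerance = 1e-9)
  expect_equal(m$perClass$F1[1], 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-9)

  set.seed(23)
  for (i in 1:100) {
    K <- sample(2:7, 1)
    cm <- matrix(rpois(K * K, sample(0:8, 1)), K,
                 dimnames = list(letters[1:K], letters[1:K]))
    if (sum(cm) == 0) cm[1, 1] <- 1L
    got <- classMetrics(cm)
    want <- bruteMetrics(cm)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-9)
    expect_equal(got$perClass$precision, want$prec, tolerance = 1e-9)
    expect_equal(got$perClass$recall, want$rec, tolerance = 1e-9)
    expect_equal(got$perClass$F1, want$f1, tolerance = 1e-9)
    expect_equal(got$macroF1, mean(want$f1), tolerance = 1e-9)
    # F1 between min and max of precision/recall, <= arithmetic mean
    ok <- want$prec + want$rec > 0
    expect_true(all(got$perClass$F1[ok] <=
                      (want$prec[ok] + want$rec[ok]) / 2 + 1e-12))
    expect_true(all(got$perClass$F1[ok] >= pmin(want$prec, want$rec)[ok] - 1e-12))
  }
  # degenerate matrices
  perfect <- diag(c(3L, 4L)); dimnames(perfect) <- list(c("a", "b"), c("a", "b"))
  expect_equal(classMetrics(perfect)$accuracy, 1)
  expect_true(all(classMetrics(perfect)$perClass$F1 == 1))
  wrong <- matrix(c(0L, 2L, 3L, 0L), 2, dimnames = dimnames(perfect))
  expect_equal(classMetrics(wrong)$accuracy, 0)
  # never-predicted class is flagged, not NaN
  mz <- classMetrics(matrix(c(2L, 1L, 0L, 0L), 2, byrow = FALSE,
                            dimnames = dimnames(perfect)))
  expect_true(mz$perClass$undefined[2])
  expect_identical(mz$perClass$F1[2], 0)
})

test_that("hierarchy collapse conserves totals and commutes", {
  hm <- hierarchyMap()
  set.seed(31)
  for (i in 1:25) {
    cm <- matrix(rpois(49, 3), 7,
                 dimnames = list(aoClasses(), aoClasses()))
    mid <- collapseConfusion(cm, hm$fineToMid)
    coarse <- collapseConfusion(mid, hm$midToCoarse)
    expect_equal(sum(mid), sum(cm))
    expect_equal(sum(coarse), sum(cm))
    expect_equal(collapseToLevel(cm, 2), coarse)
    # 2-class fracture TP = brute-force double sum over fracture pairs
    frac <- setdiff(aoClasses(), "normal")
    expect_equal(coarse["fracture", "fracture"], sum(cm[frac, frac]))
    expect_equal(coarse["normal", "fracture"], sum(cm["normal", frac]))
  }
  # within-group confusions vanish at the 3-class level
  cmA <- matrix(0L, 7, 7, dimnames = list(aoClasses(), aoClasses()))
  cmA["A1", "A2"] <- 5L
  mid <- collapseConfusion(cmA, hm$fineToMid)
  expect_equal(mid["A", "A"], 5L)
  expect_equal(sum(mid) - sum(diag(mid)), 0L)
  expect_error(collapseConfusion(matrix(1, 1, 1, dimnames = list("C1", "C1")),
                                 hm$fineToMid), "unmapped")
})

test_that("rank-based AUC equals the pairwise win probability", {
  expect_equal(rocAuc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_equal(rocAuc(c(1, 1, 0, 0), c(5, 4, 3, 2)), 1)
  expect_equal(rocAuc(c(1, 0, 1, 0), rep(0.3, 4)), 0.5)  # all ties
  expect_warning(a <- rocAuc(c(1, 1), c(0.2, 0.4)), "one class")
  expect_true(is.na(a))
  set.seed(77)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    lab <- c(0, 1, rbinom(n - 2, 1, 0.4))
    sc <- sample(round(runif(n), 2))  # rounded -> ties occur
    expect_equal(rocAuc(lab, sc), bruteAuc(lab, sc), tolerance = 1e-12)
  }
})

test_that("per-class AUC handles absent classes", {
  set.seed(8)
  probs <- randomDistributions(20, 7)
  labs <- sample(c("normal", "A1"), 20, TRUE)
  a <- multiclassAuc(labs, probs)
  expect_true(all(is.na(a[c("A2", "A3", "B1", "B2", "B3")])))
  expect_true(all(!is.na(a[c("normal", "A1")])))
})
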
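segDistPt <- function(px, py, p1, p2) {
  # point-to-segment distance (independent of the renderer's helper)
  v <- p2 - p1
  t <- max(0, min(1, sum((c(px, py) - p1) * v) / sum(v * v)))
  sqrt(sum((c(px, py) - (p1 + t * v))^2))
}

test_that("phantom rendering is deterministic and mask-consistent", {
  spec <- phantomSpec(imageSize = 64)
  a <- renderPhantom("A1", spec, seed = 42)
  b <- renderPhantom("A1", spec, seed = 42)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_true(all(a$image >= 0 & a$image <= 1))
  # normal phantoms carry no fracture mask
  nrm <- renderPhantom("normal", spec, seed = 3)
  expect_identical(sum(nrm$mask), 0)
  # every fracture class has a non-empty mask
  for (lab in setdiff(aoClasses(), "normal"))
    expect_gt(sum(renderPhantom(lab, spec, seed = 11)$mask), 0)
  expect_error(renderPhantom("C1", spec), "unknown label")
  expect_error(phantomSpec(imageSize = 32), "imageSize")
})

test_that("fracture masks land in the label's designated anatomical region", {
  spec <- phantomSpec(imageSize = 128)
  for (seed in c(1, 22, 333)) {
    for (lab in c("A1", "A2", "A3")) {
      s <- renderPhantom(lab, spec, seed)
      w <- which(s$mask > 0, arr.ind = TRUE)
      centroid <- colMeans(w) / spec$imageSize  # (y, x) in unit coords
      tr <- s$regions$trochanteric
      d <- sqrt(sum((c(centroid[2], centroid[1]) - tr$center)^2))
      expect_lt(d, tr$radius)
    }
    for (lab in c("B1", "B2", "B3")) {
      s <- renderPhantom(lab, spec, seed)
      w <- which(s$mask > 0, arr.ind = TRUE)
      centroid <- colMeans(w) / spec$imageSize
      nk <- s$regions$neck
      d <- segDistPt(centroid[2], centroid[1], nk$p1, nk$p2)
      expect_lt(d, nk$w + 0.02)
    }
  }
})

test_that("generated reports carry recoverable class keywords within the lexicon cap", {
  tpl <- reportTemplates()
  # keyword classifier recovers the class on clean templates (>= 99%)
  n <- 0; hit <- 0
  lex <- character()
  for (i in 1:200) {
    lab <- aoClasses()[(i %% 7) + 1]
    txt <- generateReport(lab, tpl, seed = i)
    n <- n + 1
    hit <- hit + (keywordClassifyReport(txt) == lab)
    lex <- union(lex, tokenizeReport(txt))
  }
  expect_gte(hit / n, 0.99)
  expect_lte(length(lex), 457)
  expect_error(generateReport("C2", tpl), "template")
  # determinism
  expect_identical(generateReport("B2", tpl, seed = 5),
                   generateReport("B2", tpl, seed = 5))
})

test_that("dataset generation reproduces split bookkeeping and pairing rules", {
  man <- tinyDataset(seed = 55L)
  rec <- manifestRecords(man)
  expect_identical(as.integer(table(rec$split)[c("train", "val", "test")]),
                   c(18L, 6L, 9L))
  # reports exist exactly for training records
  expect_true(all(!is.na(rec$report[rec$split == "train"])))
  expect_true(all(is.na(rec$report[rec$split != "train"])))
  expect_true(all(file.exists(file.path(man@meta$dir, rec$image))))
  # regenerating with the same seed gives an identical manifest
  man2 <- tinyDataset(seed = 55L)
  expect_identical(manifestRecords(man2)[, c("id", "label", "split")],
                   rec[, c("id", "label", "split")])
  # round trip through the manifest file
  path <- file.path(man@meta$dir, "manifest.tsv")
  back <- readManifest(path)
  expect_identical(manifestRecords(back)$id, rec$id)
  expect_identical(manifestRecords(back)$report, rec$report)
})

test_that("geometric transforms behave as rotate/scale/translate about center", {
  set.seed(66)
  img <- matrix(runif(64 * 64), 64, 64)
  # identity transform is pixel-exact
  expect_equal(applyTransform(img, 0, 100, 0, 0), img, tolerance = 1e-12)
  # pure translation shifts content; cross-correlation peaks at the lag
  sh <- applyTransform(img, 0, 100, 3, 0)
  expect_equal(sh[, 10:60], img[, 7:57], tolerance = 1e-9)
  shr <- applyTransform(img, 0, 100, 0, -4)
  expect_equal(shr[10:60, ], img[14:64, ], tolerance = 1e-9)
  # rotation followed by its inverse restores the interior
  smooth <- matrix(0, 64, 64)
  for (i in 1:64) for (j in 1:64)
    smooth[i, j] <- sin(i / 7) * cos(j / 9)
  r1 <- applyTransform(smooth, 10, 100, 0, 0)
  r2 <- applyTransform(r1, -10, 100, 0, 0)
  core <- 16:48
  expect_lt(max(abs(r2[core, core] - smooth[core, core])), 0.03)
  # off-grid parameters are rejected
  expect_error(applyTransform(img, 11, 100, 0, 0), "grid")
  expect_error(applyTransform(img, 2.5, 100, 0, 0), "grid")
  expect_error(applyTransform(img, 0, 85, 0, 0), "grid")
})

test_that("augmentation expands fracture classes exactly and spares the rest", {
  man <- tinyDataset(seed = 77L)
  aug <- augmentDataset(man, augmentationPolicy(), seed = 5)
  rec0 <- manifestRecords(man)
  rec <- manifestRecords(aug)
  t0 <- table(rec0$label[rec0$split == "train"])
  t1 <- table(rec$label[rec$split == "train"])
  expect_identical(t1[["normal"]], t0[["normal"]])
  for (lab in c("A1", "B2"))
    expect_identical(t1[[lab]], 4L * t0[[lab]])
  # validation and test splits are untouched
  expect_identical(rec[rec$split != "train", ], rec0[rec0$split != "train", ])
  # factor 1 leaves the manifest unchanged
  same <- augmentDataset(man, augmentationPolicy(expansionFactor = 1), seed = 5)
  expect_identical(manifestRecords(same), rec0)
  # determinism
  aug2 <- augmentDataset(man, augmentationPolicy(), seed = 5)
  expect_identical(manifestRecords(aug2), rec)
  expect_error(augmentationPolicy(rotation = integer()), "non-empty")
})
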
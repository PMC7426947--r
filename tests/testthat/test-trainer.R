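# Micro-scale training runs: the point is protocol and reproducibility
# contracts, not accuracy.

test_that("baseline training reduces the loss, ignores reports, and is reproducible", {
  man <- tinyDataset(seed = 201L)
  cfg <- microConfig(epochs = 3L)
  m1 <- trainBaseline(man, cfg)
  lg <- trainLog(m1)
  expect_identical(nrow(lg), 3L)
  expect_lt(lg$loss_total[3], lg$loss_total[1])
  expect_true(all(lg$loss_encdec == 0))
  # deterministic rerun
  m2 <- trainBaseline(man, cfg)
  expect_equal(trainLog(m2)$loss_total, lg$loss_total, tolerance = 1e-6)
  expect_identical(m1@params, m2@params)
  # removing every report leaves baseline training unaffected
  rec <- manifestRecords(man)
  unlink(file.path(man@meta$dir, rec$report[!is.na(rec$report)]))
  noRep <- new("DatasetManifest",
               records = transform(rec, report = NA_character_),
               seed = man@seed, meta = man@meta)
  m3 <- trainBaseline(noRep, cfg)
  expect_equal(trainLog(m3)$loss_total, lg$loss_total, tolerance = 1e-6)
  # empty training split errors
  valOnly <- new("DatasetManifest",
                 records = rec[rec$split != "train", ],
                 seed = man@seed, meta = man@meta)
  expect_error(trainBaseline(valOnly, cfg), "empty training split")
})

test_that("M1 trains its stages separately with a frozen encoder", {
  man <- tinyDataset(seed = 202L)
  cfg <- microConfig(epochs = 2L)
  m <- trainM1(man, cfg)
  lg <- trainLog(m)
  s1 <- lg[lg$stage == "m1-stage1", ]
  s2 <- lg[lg$stage == "m1-stage2", ]
  expect_identical(nrow(s1), 2L)
  expect_identical(nrow(s2), 2L)
  # stage 1 logs no classifier loss; stage 2 logs no reconstruction updates
  expect_true(all(is.na(s1$loss_cls)))
  expect_true(all(is.na(s2$loss_encdec)))
  expect_equal(s1$loss_total, s1$loss_encdec)
  # frozen encoder: stage-2 length does not change the encoder weights,
  # so latent codes for a fixed image are identical across stage-2 epochs
  cfgLong <- microConfig(epochs = 2L, stage2Epochs = 4L)
  mLong <- trainM1(man, cfgLong)
  img <- readImage(file.path(man@meta$dir,
                             manifestRecords(man)$image[1]))
  expect_identical(latentCodes(m, img), latentCodes(mLong, img))
  # unpaired training data is rejected
  rec <- manifestRecords(man)
  rec$report[1] <- NA_character_
  broken <- new("DatasetManifest", records = rec, seed = man@seed,
                meta = man@meta)
  expect_error(trainM1(broken, cfg), "unpaired")
})

test_that("M1 stage-1 reconstruction beats chance on a toy paired set", {
  man <- tinyDataset(seed = 203L)
  cfg <- microConfig(epochs = 6L, stage2Epochs = 1L)
  m <- trainM1(man, cfg)
  # teacher-forced token accuracy on the training reports
  h <- asNamespace("hipfrax")
  tr <- h$loadSplit(man, "train", 64)
  text <- h$prepareTextWithEmb(tr$rec, man@meta$dir, cfg)
  z <- latentCodes(m, tr$images)
  probs <- decoderForward(m@params, z, text$idMat, text$lengths,
                          cfg = m@configs$decoder)
  B <- nrow(text$idMat); Tn <- ncol(text$idMat)
  hits <- 0; tot <- 0
  for (b in seq_len(B)) for (t in seq_len(text$lengths[b])) {
    hits <- hits + (which.max(probs[b, t, ]) - 1L == text$idMat[b, t])
    tot <- tot + 1
  }
  expect_gt(hits / tot, 1 / vocabSize(m@vocab))
})

test_that("M2 with lambda = 0 reproduces baseline updates on a shared batch", {
  man <- tinyDataset(counts = list(train = c(normal = 3, A1 = 3),
                                   val = c(normal = 1),
                                   test = c(normal = 1)),
                     seed = 204L)
  cfg <- microConfig(epochs = 1L)
  cfg$batchSize <- 6L   # single batch per epoch: identical orderings
  cfg$lambda <- 0
  mBase <- trainBaseline(man, cfg)
  mJoint <- trainM2(man, cfg)
  encNames <- grep("^(enc|cls)_", names(mBase@params), value = TRUE)
  for (nm in encNames)
    expect_equal(mJoint@params[[nm]], mBase@params[[nm]], tolerance = 1e-12)
  # bookkeeping identity: total = cls + lambda * encdec at every logged epoch
  cfg2 <- microConfig(epochs = 2L)
  cfg2$lambda <- 0.5
  mj <- trainM2(man, cfg2)
  lg <- trainLog(mj)
  expect_equal(lg$loss_total, lg$loss_cls + 0.5 * lg$loss_encdec,
               tolerance = 1e-9)
})

test_that("cross-validation partitions the paired set deterministically", {
  man <- tinyDataset(counts = list(train = c(normal = 5, A1 = 5, B2 = 5),
                                   val = c(normal = 1),
                                   test = c(normal = 1)),
                     seed = 205L)
  cfg <- microConfig(epochs = 1L)
  cv <- crossValidate(man, cfg, k = 5L)
  expect_identical(nrow(cv$perFold), 5L)
  expect_identical(sum(cv$perFold$n), 15L)
  # every paired sample appears in exactly one fold
  expect_identical(sort(unique(cv$assignments)), 1:5)
  expect_identical(length(cv$assignments), 15L)
  expect_true(all(table(cv$assignments) == 3))
  # deterministic fold assignment under the seed
  cv2 <- crossValidate(man, cfg, k = 5L)
  expect_identical(cv2$assignments, cv$assignments)
  # mean equals the arithmetic mean of fold metrics
  expect_equal(unname(cv$mean["accuracy"]), mean(cv$perFold$accuracy))
  expect_error(crossValidate(man, cfg, k = 30L), "exceed")
  expect_error(crossValidate(man, cfg, k = 1L), "k must be")
})
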
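h <- asNamespace("hipfrax")

# small encoder for fast checks (16 px collapses to 1x1 after four pools)
tinyEnc <- function(backbone = "small-cnn", dropout = 0)
  encoderConfig(inputSize = 16, backbone = backbone, latentDim = 8,
                dropout = dropout)

test_that("encoder meets its shape, determinism and finiteness contracts", {
  set.seed(1)
  cfg <- tinyEnc()
  params <- h$initEncoderParams(cfg)
  imgs <- lapply(1:8, function(i) matrix(runif(256), 16, 16))
  z <- encoderForward(params, imgs, cfg)
  expect_identical(dim(z), c(8L, 8L))
  expect_true(all(is.finite(z)))
  # eval mode is deterministic
  expect_identical(z, encoderForward(params, imgs, cfg))
  # train mode with dropout is not a pure function of the image
  cfgD <- tinyEnc(dropout = 0.5)
  z1 <- encoderForward(params, imgs, cfgD, trainMode = TRUE)
  z2 <- encoderForward(params, imgs, cfgD, trainMode = TRUE)
  expect_false(identical(z1, z2))
  expect_error(encoderForward(params, matrix(0, 8, 8), cfg), "16 x 16")
})

test_that("forward passes stay finite across many random inputs", {
  cfg <- tinyEnc()
  for (s in 1:100) {
    set.seed(s)
    params <- h$initEncoderParams(cfg)
    cp <- h$initClassifierParams(classifierConfig(hidden = 6, classes = 7), 8)
    img <- matrix(runif(256), 16, 16)
    z <- encoderForward(params, img, cfg)
    logits <- classifierForward(cp, z)
    expect_true(all(is.finite(z)) && all(is.finite(logits)))
  }
})

test_that("backpropagated gradients match finite differences", {
  set.seed(21)
  cfg <- tinyEnc()
  params <- h$initEncoderParams(cfg)
  params <- c(params, h$initClassifierParams(classifierConfig(hidden = 5,
                                                             classes = 3), 8))
  B <- 2
  X <- matrix(runif(2 * 256), ncol = 1)
  y <- c(0L, 2L)
  Y <- matrix(0, B, 3); Y[cbind(1:B, y + 1)] <- 1
  lossAt <- function(p, Xm) {
    ef <- h$encoderForwardCore(p, Xm, B, cfg, train = FALSE)
    cf <- h$classifierForwardCore(p, ef$z)
    classifierLoss(h$softmaxRows(cf$logits), Y)
  }
  ef <- h$encoderForwardCore(params, X, B, cfg, train = FALSE)
  cf <- h$classifierForwardCore(params, ef$z)
  dlogits <- (h$softmaxRows(cf$logits) - Y) / B
  cb <- h$classifierBackwardCore(params, cf$cache, dlogits)
  eb <- h$encoderBackwardCore(params, ef$cache, cb$dz, wantInput = TRUE)
  g <- c(cb$grads, eb$grads)
  eps <- 1e-6
  for (nm in c("enc_L1_W", "enc_L5_W", "enc_fc_W", "cls_W1", "cls_b2")) {
    for (i in sample(length(params[[nm]]), 2)) {
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (lossAt(p2, X) - lossAt(p3, X)) / (2 * eps)
      if (abs(num) > 1e-8)
        expect_lt(abs(num - g[[nm]][i]) / abs(num), 1e-4)
    }
  }
  # gradient w.r.t. an input pixel (the image saliency path)
  px <- which(abs(eb$dInput) > 1e-6)[1:3]
  for (i in px) {
    X2 <- X; X2[i] <- X2[i] + eps
    X3 <- X; X3[i] <- X3[i] - eps
    num <- (lossAt(params, X2) - lossAt(params, X3)) / (2 * eps)
    expect_lt(abs(num - eb$dInput[i]) / abs(num), 1e-4)
  }
})

test_that("decoder emits normalized per-step distributions conditioned on z", {
  set.seed(31)
  dcfg <- decoderConfig(steps = 40, embedDim = 6, hidden = 5, vocabSize = 9,
                        dropout = 0)
  dp <- h$initDecoderParams(dcfg, latentDim = 8)
  z <- matrix(rnorm(2 * 8), 2, 8)
  ids <- matrix(sample(0:8, 80, TRUE), 2, 40)
  probs <- decoderForward(dp, z, ids, cfg = dcfg)
  expect_identical(dim(probs), c(2L, 40L, 9L))
  sums <- apply(probs, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(probs >= 0))
  # different latent codes give different distributions (conditioning live)
  z2 <- z + matrix(rnorm(16), 2, 8)
  probs2 <- decoderForward(dp, z2, ids, cfg = dcfg)
  expect_gt(max(abs(probs - probs2)), 1e-6)
  # 40 output steps regardless of true report length
  probs3 <- decoderForward(dp, z, ids, lengths = c(3L, 7L), cfg = dcfg)
  expect_identical(dim(probs3), c(2L, 40L, 9L))
  expect_error(decoderForward(dp, matrix(0, 2, 5), ids, cfg = dcfg),
               "latent dimension")
})

test_that("classifier is a two-layer map with the documented contracts", {
  set.seed(41)
  cp <- h$initClassifierParams(classifierConfig(hidden = 10, classes = 7), 8)
  z <- matrix(rnorm(8 * 8), 8, 8)
  logits <- classifierForward(cp, z)
  expect_identical(dim(logits), c(8L, 7L))
  expect_identical(logits, classifierForward(cp, z))  # eval determinism
  # zero weights -> constant logits equal to the output biases
  cp0 <- cp
  cp0$cls_W1[] <- 0; cp0$cls_W2[] <- 0; cp0$cls_b1[] <- 0
  cp0$cls_b2 <- rnorm(7)
  l0 <- classifierForward(cp0, z)
  for (b in 1:8) expect_equal(l0[b, ], cp0$cls_b2, tolerance = 1e-12)
})

test_that("prediction is an image-only probability vector", {
  set.seed(51)
  cfg <- tinyEnc()
  params <- c(h$initEncoderParams(cfg),
              h$initClassifierParams(classifierConfig(), 8))
  model <- new("FractureNet", params = params,
               configs = list(encoder = cfg, decoder = NULL,
                              classifier = classifierConfig(), train = list()),
               vocab = NULL, regime = "baseline", seed = 1L,
               log = data.frame())
  img <- matrix(runif(256), 16, 16)
  p <- predictImage(model, img)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_identical(names(p), aoClasses())
  # uniform logits -> uniform probabilities
  pz <- params
  pz$cls_W1[] <- 0; pz$cls_W2[] <- 0; pz$cls_b1[] <- 0; pz$cls_b2[] <- 0
  model0 <- new("FractureNet", params = pz, configs = model@configs,
                vocab = NULL, regime = "baseline", seed = 1L,
                log = data.frame())
  expect_equal(unname(predictImage(model0, img)), rep(1 / 7, 7),
               tolerance = 1e-12)
  empty <- new("FractureNet", params = list(), configs = model@configs,
               vocab = NULL, regime = "baseline", seed = 1L,
               log = data.frame())
  expect_error(predictImage(empty, img), "no trained parameters")
})

test_that("backbone swap preserves the interface contract", {
  set.seed(61)
  for (bb in c("small-cnn", "inception-like")) {
    cfg <- tinyEnc(backbone = bb)
    params <- h$initEncoderParams(cfg)
    z <- encoderForward(params, matrix(runif(256), 16, 16), cfg)
    expect_identical(dim(z), c(1L, 8L))
    expect_true(all(is.finite(z)))
  }
  expect_error(encoderConfig(backbone = "resnet"), "unknown backbone")
})

test_that("checkpoints round-trip through the binary format", {
  set.seed(71)
  cfg <- tinyEnc()
  vocab <- buildVocabulary(list(c("neck", "fracture")), maxSize = 10)
  params <- c(h$initEncoderParams(cfg),
              h$initClassifierParams(classifierConfig(), 8))
  model <- new("FractureNet", params = params,
               configs = list(encoder = cfg, decoder = NULL,
                              classifier = classifierConfig(),
                              train = list(seed = 1L)),
               vocab = vocab, regime = "m2", seed = 9L,
               log = data.frame(stage = "m2-joint", epoch = 1L,
                                loss_total = 1.5))
  path <- tempfile(fileext = ".ckpt")
  saveCheckpoint(model, path)
  back <- readCheckpoint(path)
  expect_identical(back@params, model@params)
  expect_identical(back@regime, "m2")
  expect_identical(back@seed, 9L)
  expect_identical(back@vocab@tokens, vocab@tokens)
  img <- matrix(runif(256), 16, 16)
  expect_equal(predictImage(back, img), predictImage(model, img),
               tolerance = 1e-12)
  expect_error(readCheckpoint(tempfile()), "not found")
})
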
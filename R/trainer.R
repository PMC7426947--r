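## Training regimes.
##
## baseline: image-only encoder + classifier (reports ignored).
## m1:       stage 1 trains encoder + report decoder on the reconstruction
##           loss only; stage 2 trains the classifier on the (by default
##           frozen) encoder's latent codes.
## m2:       joint loss L = L_cls + lambda * L_encoder-decoder each step;
##           both heads update the shared latent.
##
## A single master seed fans out (via deriveSeed) to weight initialization,
## data shuffling, dropout masks and the embedding pre-fit, so runs are
## reproducible bit-for-bit at a fixed thread count.

#' Training configuration
#'
#' @param regime `"baseline"`, `"m1"` or `"m2"`.
#' @param epochs epochs per stage (default 30).
#' @param batchSize minibatch size (default 16).
#' @param lr Adam learning rate (default 1e-4).
#' @param lambda reconstruction weight in the joint loss (default 0.5).
#' @param lossType classification loss: `"focal"` (default) or `"ce"`.
#' @param gamma focal focusing parameter (default 2).
#' @param alpha `"invfreq"` (inverse class frequency normalized to mean 1,
#'   the default), `"none"`, or an explicit length-7 weight vector.
#' @param seed master seed.
#' @param stage2Epochs epochs for M1 stage 2 (default: same as `epochs`).
#' @param selectBest return the parameters of the epoch with the best
#'   validation accuracy instead of the last epoch's (default TRUE; has no
#'   effect when the manifest has no validation split). Training always
#'   runs the full schedule; this is checkpoint selection, not early
#'   stopping.
#' @param freezeEncoder freeze the encoder in M1 stage 2 (default TRUE).
#' @param encoder an [encoderConfig()].
#' @param classifier a [classifierConfig()].
#' @param decoderHidden LSTM hidden units per direction (default 128).
#' @param embedDim word-embedding dimension (default 128).
#' @param maxLen report length cap in tokens (default 40).
#' @param vocabMax vocabulary frequency cap (default 300).
#' @param embedInit `"glove"` (co-occurrence pre-fit, fine-tuned; default)
#'   or `"random"`.
#' @param gloveEpochs epochs for the embedding pre-fit (default 30).
#' @param projectCell project the latent to the initial LSTM cell states as
#'   well as the hidden states (default TRUE).
#' @return a `TrainConfig` list.
#' @export
trainConfig <- function(regime = c("baseline", "m1", "m2"), epochs = 30L,
                        batchSize = 16L, lr = 1e-4, lambda = 0.5,
                        lossType = c("focal", "ce"), gamma = 2,
                        alpha = "invfreq", seed = 1L, stage2Epochs = NULL,
                        selectBest = TRUE, freezeEncoder = TRUE,
                        encoder = encoderConfig(),
                        classifier = classifierConfig(),
                        decoderHidden = 128L, embedDim = 128L, maxLen = 40L,
                        vocabMax = 300L, embedInit = "glove",
                        gloveEpochs = 30L, projectCell = TRUE) {
  regime <- match.arg(regime)
  if (lr <= 0) stop("learning rate must be > 0")
  if (epochs < 1L) stop("epochs must be >= 1")
  list(regime = regime, epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), lr = lr, lambda = lambda,
       lossType = match.arg(lossType), gamma = gamma, alpha = alpha,
       seed = as.integer(seed),
       stage2Epochs = as.integer(stage2Epochs %||% epochs),
       selectBest = isTRUE(selectBest),
       freezeEncoder = isTRUE(freezeEncoder),
       encoder = encoder, classifier = classifier,
       decoderHidden = as.integer(decoderHidden),
       embedDim = as.integer(embedDim), maxLen = as.integer(maxLen),
       vocabMax = as.integer(vocabMax), embedInit = embedInit,
       gloveEpochs = as.integer(gloveEpochs),
       projectCell = isTRUE(projectCell))
}

# Load a split's images (and labels) from a manifest into memory.
loadSplit <- function(manifest, split, inputSize) {
  rec <- manifest@records[manifest@records$split == split, , drop = FALSE]
  dir <- manifest@meta$dir
  images <- lapply(rec$image, function(p) {
    im <- readImage(file.path(dir, p))
    if (!all(dim(im) == inputSize))
      stop(sprintf("image %s is not %d x %d", p, inputSize, inputSize))
    im
  })
  list(rec = rec, images = images,
       y = match(rec$label, aoClasses()) - 1L)
}

# Tokenize the paired reports of the training split and build the text-side
# assets: vocabulary, padded id matrix, lengths, optional GloVe-initialized
# embedding matrix (rescaled to a sane activation magnitude).
prepareTextWithEmb <- function(trainRec, dir, config) {
  if (anyNA(trainRec$report))
    stop("unpaired training records: every training record needs a report")
  texts <- vapply(trainRec$report,
                  function(p) paste(readLines(file.path(dir, p),
                                              warn = FALSE), collapse = " "),
                  character(1))
  tokens <- lapply(texts, tokenizeReport)
  vocab <- buildVocabulary(tokens, maxSize = config$vocabMax)
  ids <- lapply(tokens, function(tk) tokenIds(vocab, head(tk, config$maxLen)))
  lens <- lengths(ids)
  Tmax <- max(lens)
  idMat <- t(vapply(ids, function(v) c(v, rep(0L, Tmax - length(v))),
                    integer(Tmax)))
  emb <- NULL
  if (identical(config$embedInit, "glove")) {
    cooc <- buildCooccurrence(tokens, vocab, window = 5L)
    fit <- fitGlove(cooc, d = config$embedDim, epochs = config$gloveEpochs,
                    seed = deriveSeed(config$seed, "glove"))
    emb <- fit$vectors * 0.1 / max(1e-9, stats::sd(fit$vectors))  # rescale
  }
  list(vocab = vocab, idMat = idMat, lengths = as.integer(lens), emb = emb)
}

focalAlphaVec <- function(config, labels) {
  if (identical(config$alpha, "none")) return(NULL)
  if (is.numeric(config$alpha)) return(config$alpha)
  unname(inverseFrequencyAlpha(labels))
}

# Classification loss value and gradient w.r.t. logits (batch mean).
clsLossGrad <- function(logits, y, config, alphaVec) {
  B <- nrow(logits)
  K <- ncol(logits)
  probs <- softmaxRows(logits)
  Y <- matrix(0, B, K); Y[cbind(seq_len(B), y + 1L)] <- 1
  if (config$lossType == "ce") {
    loss <- classifierLoss(probs, Y)
    dlogits <- (probs - Y) / B
  } else {
    loss <- focalLoss(probs, Y, gamma = config$gamma, alpha = alphaVec)
    pt <- pmax(rowSums(probs * Y), EPS_LOG)
    at <- if (is.null(alphaVec)) rep(1, B) else alphaVec[y + 1L]
    gmm <- config$gamma
    # d/dp of -a (1-p)^g log p, times p (chain through softmax)
    coef <- -at * (-gmm * (1 - pt)^pmax(gmm - 1, 0) * log(pt) +
                   (1 - pt)^gmm / pt) * pt
    dlogits <- (coef / B) * (Y - probs)
    # note: dp/dlogit_j = p (delta_tj - y_j), so dlogits = coef*(delta - y)/B
  }
  list(loss = loss, dlogits = dlogits, probs = probs)
}

# Reconstruction loss value and gradient w.r.t. decoder logits for a batch.
# Reduction: per-step cross-entropy averaged over each report's real tokens,
# then over the batch (the framework-default reduction the joint weight
# lambda is calibrated against); the summed-over-steps scalar is available
# as encoderDecoderLoss(). Per-token normalization keeps the reconstruction
# gradient on the same scale as the classification gradient regardless of
# report length.
decLossGrad <- function(probs, idMat, lengths) {
  B <- nrow(idMat); Tn <- ncol(idMat); V <- ncol(probs)
  tmat <- matrix(rep(seq_len(Tn), each = B), B, Tn)
  w <- (tmat <= matrix(rep(lengths, Tn), B, Tn)) /
    matrix(rep(lengths, Tn), B, Tn)
  flatTarget <- as.vector(idMat) + 1L
  rows <- seq_len(B * Tn)
  pTarget <- pmax(probs[cbind(rows, flatTarget)], EPS_LOG)
  wVec <- as.vector(w)
  loss <- sum(-log(pTarget) * wVec) / B
  Y <- matrix(0, B * Tn, V)
  Y[cbind(rows, flatTarget)] <- 1
  dlogits <- (probs - Y) * wVec / B
  list(loss = loss, dlogits = dlogits)
}

evalAccuracy <- function(params, cfgEnc, images, y, batchSize = 32L) {
  if (!length(images)) return(NA_real_)
  n <- length(images)
  correct <- 0L
  for (s in seq(1L, n, by = batchSize)) {
    idx <- s:min(n, s + batchSize - 1L)
    z <- encoderForward(params, images[idx], cfgEnc)
    pred <- max.col(classifierForwardCore(params, z)$logits) - 1L
    correct <- correct + sum(pred == y[idx])
  }
  correct / n
}

newLogRow <- function(stage, epoch, total, cls, ed, trainAcc, valAcc, seed) {
  data.frame(stage = stage, epoch = epoch, loss_total = total,
             loss_cls = cls, loss_encdec = ed, train_acc = trainAcc,
             val_acc = valAcc, seed = seed,
             timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
             stringsAsFactors = FALSE)
}

# Shared minibatch engine. `step(idx)` must return list(lossTotal, lossCls,
# lossEd, nCorrect) and update params/opt state in its enclosing env.
# `snapshotFun`, when given, is called after epochs whose validation
# accuracy improves (checkpoint selection on the validation split).
runEpochs <- function(stage, epochs, n, batchSize, stepFun, evalFun, seed,
                      snapshotFun = NULL) {
  log <- NULL
  bestVal <- -Inf
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- cls <- ed <- 0; corr <- 0L; nb <- 0L
    for (s in seq(1L, n, by = batchSize)) {
      idx <- ord[s:min(n, s + batchSize - 1L)]
      r <- stepFun(idx)
      tot <- tot + r$lossTotal; cls <- cls + r$lossCls; ed <- ed + r$lossEd
      corr <- corr + r$nCorrect; nb <- nb + 1L
    }
    valAcc <- evalFun()
    if (!is.null(snapshotFun) && !is.na(valAcc) && valAcc > bestVal) {
      bestVal <- valAcc
      snapshotFun(ep)
    }
    log <- rbind(log, newLogRow(stage, ep, tot / nb, cls / nb, ed / nb,
                                corr / n, valAcc, seed))
  }
  log
}

trainModel <- function(manifest, config) {
  regime <- config$regime
  needText <- regime %in% c("m1", "m2")
  enc <- config$encoder
  tr <- loadSplit(manifest, "train", enc$inputSize)
  if (!nrow(tr$rec)) stop("empty training split")
  va <- loadSplit(manifest, "val", enc$inputSize)
  text <- NULL; decCfg <- NULL
  if (needText) {
    text <- prepareTextWithEmb(tr$rec, manifest@meta$dir, config)
    decCfg <- decoderConfig(steps = config$maxLen, embedDim = config$embedDim,
                            hidden = config$decoderHidden,
                            vocabSize = vocabSize(text$vocab),
                            projectCell = config$projectCell,
                            dropout = enc$dropout,
                            embedInit = config$embedInit)
  }
  clsCfg <- config$classifier
  alphaVec <- focalAlphaVec(config, tr$rec$label)
  n <- length(tr$images)

  params <- withr::with_seed(deriveSeed(config$seed, "init"), {
    p <- initEncoderParams(enc)
    p <- c(p, initClassifierParams(clsCfg, enc$latentDim))
    if (needText) p <- c(p, initDecoderParams(decCfg, enc$latentDim,
                                              emb = text$emb))
    p
  })

  imageMat <- function(idx)
    matrix(unlist(tr$images[idx], use.names = FALSE), ncol = 1L)

  log <- withr::with_seed(deriveSeed(config$seed, "train"), {
    opt <- adamInit(params)
    doStep <- function(grads) {
      upd <- adamStep(params, grads, opt, lr = config$lr)
      params <<- upd$params; opt <<- upd$state
    }
    evalFun <- function() evalAccuracy(params, enc, va$images, va$y)
    bestParams <- NULL
    snap <- if (config$selectBest) function(ep) bestParams <<- params
            else NULL

    if (regime == "baseline") {
      stepFun <- function(idx) {
        ef <- encoderForwardCore(params, imageMat(idx), length(idx), enc,
                                 train = TRUE)
        cf <- classifierForwardCore(params, ef$z)
        cl <- clsLossGrad(cf$logits, tr$y[idx], config, alphaVec)
        cb <- classifierBackwardCore(params, cf$cache, cl$dlogits)
        eb <- encoderBackwardCore(params, ef$cache, cb$dz)
        doStep(c(cb$grads, eb$grads))
        list(lossTotal = cl$loss, lossCls = cl$loss, lossEd = 0,
             nCorrect = sum(max.col(cl$probs) - 1L == tr$y[idx]))
      }
      log <- runEpochs("baseline", config$epochs, n, config$batchSize,
                       stepFun, evalFun, config$seed, snap)
      if (!is.null(bestParams)) params <- bestParams
      log
    } else if (regime == "m2") {
      lambda <- config$lambda
      stepFun <- function(idx) {
        ef <- encoderForwardCore(params, imageMat(idx), length(idx), enc,
                                 train = TRUE)
        cf <- classifierForwardCore(params, ef$z)
        cl <- clsLossGrad(cf$logits, tr$y[idx], config, alphaVec)
        cb <- classifierBackwardCore(params, cf$cache, cl$dlogits)
        lens <- text$lengths[idx]
        Tb <- max(lens)
        df <- decoderForwardCore(params, ef$z,
                                 text$idMat[idx, seq_len(Tb), drop = FALSE],
                                 lens, decCfg, train = TRUE)
        dl <- decLossGrad(df$probs, text$idMat[idx, seq_len(Tb), drop = FALSE],
                          lens)
        db <- decoderBackwardCore(params, df$cache, lambda * dl$dlogits,
                                  decCfg)
        dz <- cb$dz + db$dz
        eb <- encoderBackwardCore(params, ef$cache, dz)
        doStep(c(cb$grads, db$grads, eb$grads))
        list(lossTotal = jointLoss(cl$loss, dl$loss, lambda),
             lossCls = cl$loss, lossEd = dl$loss,
             nCorrect = sum(max.col(cl$probs) - 1L == tr$y[idx]))
      }
      log <- runEpochs("m2-joint", config$epochs, n, config$batchSize,
                       stepFun, evalFun, config$seed, snap)
      if (!is.null(bestParams)) params <- bestParams
      log
    } else {  # m1: two stages
      stepFun1 <- function(idx) {
        ef <- encoderForwardCore(params, imageMat(idx), length(idx), enc,
                                 train = TRUE)
        lens <- text$lengths[idx]
        Tb <- max(lens)
        df <- decoderForwardCore(params, ef$z,
                                 text$idMat[idx, seq_len(Tb), drop = FALSE],
                                 lens, decCfg, train = TRUE)
        dl <- decLossGrad(df$probs, text$idMat[idx, seq_len(Tb), drop = FALSE],
                          lens)
        db <- decoderBackwardCore(params, df$cache, dl$dlogits, decCfg)
        eb <- encoderBackwardCore(params, ef$cache, db$dz)
        doStep(c(db$grads, eb$grads))
        list(lossTotal = dl$loss, lossCls = NA_real_, lossEd = dl$loss,
             nCorrect = 0L)
      }
      log1 <- runEpochs("m1-stage1", config$epochs, n, config$batchSize,
                        stepFun1, function() NA_real_, config$seed)
      log1$train_acc <- NA_real_

      if (config$freezeEncoder) {
        # frozen encoder: latent codes computed once, in eval mode
        zAll <- encoderForward(params, tr$images, enc)
        stepFun2 <- function(idx) {
          cf <- classifierForwardCore(params, zAll[idx, , drop = FALSE])
          cl <- clsLossGrad(cf$logits, tr$y[idx], config, alphaVec)
          cb <- classifierBackwardCore(params, cf$cache, cl$dlogits)
          doStep(cb$grads)
          list(lossTotal = cl$loss, lossCls = cl$loss, lossEd = NA_real_,
               nCorrect = sum(max.col(cl$probs) - 1L == tr$y[idx]))
        }
      } else {
        stepFun2 <- function(idx) {
          ef <- encoderForwardCore(params, imageMat(idx), length(idx), enc,
                                   train = TRUE)
          cf <- classifierForwardCore(params, ef$z)
          cl <- clsLossGrad(cf$logits, tr$y[idx], config, alphaVec)
          cb <- classifierBackwardCore(params, cf$cache, cl$dlogits)
          eb <- encoderBackwardCore(params, ef$cache, cb$dz)
          doStep(c(cb$grads, eb$grads))
          list(lossTotal = cl$loss, lossCls = cl$loss, lossEd = NA_real_,
               nCorrect = sum(max.col(cl$probs) - 1L == tr$y[idx]))
        }
      }
      log2 <- runEpochs("m1-stage2",
                        config$stage2Epochs %||% config$epochs, n,
                        config$batchSize, stepFun2, evalFun, config$seed,
                        snap)
      if (!is.null(bestParams)) params <- bestParams
      rbind(log1, log2)
    }
  })

  new("FractureNet", params = params,
      configs = list(encoder = enc, decoder = decCfg, classifier = clsCfg,
                     train = config[setdiff(names(config),
                                            c("encoder", "classifier"))]),
      vocab = if (needText) text$vocab else NULL,
      regime = regime, seed = config$seed, log = log)
}

#' Train the image-only baseline
#'
#' Encoder + classifier on the classification loss only; report files are
#' never consulted.
#'
#' @param manifest a [DatasetManifest-class] with a training split.
#' @param config a [trainConfig()] (its `regime` is overridden).
#' @return a trained [FractureNet-class] with the training log in
#'   [trainLog()].
#' @export
trainBaseline <- function(manifest, config = trainConfig()) {
  config$regime <- "baseline"
  trainModel(manifest, config)
}

#' Train M1: encoder-decoder first, then the classifier on the latent
#'
#' Stage 1 minimizes only the report-reconstruction loss. Stage 2 trains the
#' classifier on the shared latent representation; with
#' `config$freezeEncoder` (the default) the encoder is frozen so its latent
#' code for a fixed image is identical across stage-2 epochs.
#'
#' @inheritParams trainBaseline
#' @export
trainM1 <- function(manifest, config = trainConfig()) {
  config$regime <- "m1"
  trainModel(manifest, config)
}

#' Train M2: jointly learned classification and report restoration
#'
#' Minimizes `L_cls + lambda * L_encoder-decoder` at every step; both heads
#' update the shared latent code.
#'
#' @inheritParams trainBaseline
#' @export
trainM2 <- function(manifest, config = trainConfig()) {
  config$regime <- "m2"
  trainModel(manifest, config)
}

#' K-fold cross-validation over the paired training set
#'
#' Folds partition the paired (image + report) records; each sample is
#' validated exactly once. For each fold the configured regime is trained on
#' the remaining folds and evaluated (image-only) on the held-out fold.
#' Fold assignment is deterministic under `config$seed`.
#'
#' @param manifest a [DatasetManifest-class]; only its paired training
#'   records are used.
#' @param config a [trainConfig()].
#' @param k number of folds (default 5).
#' @return list with `assignments` (record id -> fold), `perFold`
#'   data.frame (fold, n, accuracy, macroF1) and `mean` metrics.
#' @export
crossValidate <- function(manifest, config = trainConfig(), k = 5L) {
  rec <- manifest@records
  paired <- rec[rec$split == "train" & !is.na(rec$report), , drop = FALSE]
  n <- nrow(paired)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k must not exceed the number of paired samples")
  fold <- withr::with_seed(deriveSeed(config$seed, "cv"),
                           sample(rep(seq_len(k), length.out = n)))
  perFold <- NULL
  for (f in seq_len(k)) {
    hold <- paired[fold == f, , drop = FALSE]
    keep <- paired[fold != f, , drop = FALSE]
    holdEval <- hold
    holdEval$report <- NA_character_
    holdEval$split <- "test"
    sub <- new("DatasetManifest",
               records = rbind(keep, holdEval),
               seed = manifest@seed, meta = manifest@meta)
    model <- trainModel(sub, config)
    ev <- loadSplit(sub, "test", config$encoder$inputSize)
    acc <- evalAccuracy(model@params, config$encoder, ev$images, ev$y)
    pred <- predictLabels(model, ev$images)
    cm <- confusionMatrix(ev$rec$label, pred)
    met <- classMetrics(cm)
    perFold <- rbind(perFold,
                     data.frame(fold = f, n = nrow(hold), accuracy = acc,
                                macroF1 = met$macroF1))
  }
  list(assignments = setNames(fold, paired$id), perFold = perFold,
       mean = c(accuracy = mean(perFold$accuracy),
                macroF1 = mean(perFold$macroF1)))
}

#' Predict class labels for a batch of images
#'
#' @param model a trained [FractureNet-class].
#' @param images images as accepted by [encoderForward()].
#' @return character vector of predicted [aoClasses()] labels.
#' @export
predictLabels <- function(model, images) {
  z <- latentCodes(model, images)
  aoClasses()[max.col(classifierForwardCore(model@params, z)$logits)]
}
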
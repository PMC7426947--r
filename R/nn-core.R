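## Dense/conv/LSTM building blocks with hand-written backward passes, plus
## Adam. Activations use the "NHWB matrix form" documented in src/nnops.cpp:
## a batch of B HxW C-channel maps is a (B*H*W) x C matrix with row index
## h + H*(w + W*b). All weights are plain numeric matrices in a flat named
## list, which keeps the optimizer and checkpointing trivial.

addRowVec <- function(M, v) M + rep(v, each = nrow(M))

softmaxRows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

# inverted-dropout mask drawn from the current RNG stream
dropMask <- function(n, rate) {
  if (rate <= 0) return(NULL)
  keep <- 1 - rate
  (runif(n) < keep) / keep
}

heInit <- function(nr, nc, fanIn = nr) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / fanIn)), nr, nc)
}

# --- architecture descriptions --------------------------------------------

# Sequential layer graph per backbone. conv layers are stride-1
# same-padding; every pool halves H and W; dropout (train only) follows each
# pool. The latent head is global average pooling + one fully-connected
# layer to latentDim.
archLayers <- function(backbone) {
  switch(backbone,
    "small-cnn" = list(
      list(type = "conv", k = 3L, Cout = 6L),  list(type = "pool"),
      list(type = "conv", k = 3L, Cout = 12L), list(type = "pool"),
      list(type = "conv", k = 3L, Cout = 24L), list(type = "pool"),
      list(type = "conv", k = 3L, Cout = 48L), list(type = "pool")),
    "inception-like" = list(
      list(type = "conv", k = 3L, Cout = 6L), list(type = "pool"),
      list(type = "incept", branches = list(c(k = 1L, Cout = 6L),
                                            c(k = 3L, Cout = 10L),
                                            c(k = 5L, Cout = 6L))),
      list(type = "pool"),
      list(type = "incept", branches = list(c(k = 1L, Cout = 10L),
                                            c(k = 3L, Cout = 14L),
                                            c(k = 5L, Cout = 10L))),
      list(type = "pool"),
      list(type = "conv", k = 3L, Cout = 48L), list(type = "pool")),
    stop(sprintf("unknown backbone '%s'", backbone)))
}

layerChannels <- function(layers, Cin = 1L) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") Cin <- l$Cout
    if (l$type == "incept") Cin <- sum(vapply(l$branches, function(b) b[["Cout"]], 0L))
  }
  Cin
}

#' Encoder configuration
#'
#' @param inputSize square input size in pixels (must be divisible by 16).
#' @param backbone `"small-cnn"` (4 conv/pool blocks, the desk-scale
#'   default) or `"inception-like"` (parallel 1x1/3x3/5x5 branch blocks).
#' @param latentDim shared latent dimension (default 64).
#' @param dropout dropout rate applied to the deepest (final-pool) feature
#'   maps during training (default 0.5).
#' @return an `EncoderConfig` list.
#' @export
encoderConfig <- function(inputSize = 64L, backbone = "small-cnn",
                          latentDim = 64L, dropout = 0.5) {
  if (latentDim < 2L) stop("latentDim must be >= 2")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (inputSize %% 16L != 0L) stop("inputSize must be divisible by 16")
  archLayers(backbone)  # validates backbone
  list(inputSize = as.integer(inputSize), backbone = backbone,
       latentDim = as.integer(latentDim), dropout = dropout)
}

#' Decoder configuration
#'
#' @param steps maximum unrolled sequence length (default 40, the report
#'   corpus maximum).
#' @param embedDim word-embedding dimension (default 128).
#' @param hidden LSTM hidden units per direction (default 128).
#' @param vocabSize vocabulary size V (specials included).
#' @param projectCell also project the latent code to the initial cell
#'   states (default TRUE), in addition to the initial hidden states.
#' @param dropout dropout rate (default 0.5): token-granular on the
#'   embedded inputs (whole word embeddings are blanked, making restoration
#'   cloze-like) and elementwise on the concatenated hidden states.
#' @param embedInit `"glove"` (initialize from co-occurrence embeddings,
#'   fine-tuned) or `"random"`.
#' @param embedTrain update the embedding matrix during training (default
#'   TRUE).
#' @return a `DecoderConfig` list.
#' @export
decoderConfig <- function(steps = 40L, embedDim = 128L, hidden = 128L,
                          vocabSize, projectCell = TRUE, dropout = 0.5,
                          embedInit = "glove", embedTrain = TRUE) {
  if (steps < 1L) stop("steps must be >= 1")
  list(steps = as.integer(steps), embedDim = as.integer(embedDim),
       hidden = as.integer(hidden), vocabSize = as.integer(vocabSize),
       projectCell = isTRUE(projectCell), dropout = dropout,
       embedInit = embedInit, embedTrain = isTRUE(embedTrain))
}

#' Classifier configuration
#'
#' Exactly two fully-connected layers (hidden + output) on the latent code.
#'
#' @param hidden hidden units (default 64).
#' @param classes number of classes (default 7).
#' @return a `ClassifierConfig` list.
#' @export
classifierConfig <- function(hidden = 64L, classes = 7L) {
  list(hidden = as.integer(hidden), classes = as.integer(classes))
}

# --- parameter initialization (draws from the current RNG stream) ----------

initEncoderParams <- function(cfg) {
  layers <- archLayers(cfg$backbone)
  p <- list()
  Cin <- 1L
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      p[[sprintf("enc_L%d_W", i)]] <- heInit(l$k * l$k * Cin, l$Cout)
      p[[sprintf("enc_L%d_b", i)]] <- numeric(l$Cout)
      Cin <- l$Cout
    } else if (l$type == "incept") {
      for (j in seq_along(l$branches)) {
        br <- l$branches[[j]]
        p[[sprintf("enc_L%d_b%d_W", i, j)]] <- heInit(br[["k"]]^2 * Cin, br[["Cout"]])
        p[[sprintf("enc_L%d_b%d_b", i, j)]] <- numeric(br[["Cout"]])
      }
      Cin <- sum(vapply(l$branches, function(b) b[["Cout"]], 0L))
    }
  }
  p$enc_fc_W <- heInit(Cin, cfg$latentDim, fanIn = Cin)
  p$enc_fc_b <- numeric(cfg$latentDim)
  p
}

initClassifierParams <- function(cfg, latentDim) {
  list(cls_W1 = heInit(latentDim, cfg$hidden),
       cls_b1 = numeric(cfg$hidden),
       cls_W2 = heInit(cfg$hidden, cfg$classes),
       cls_b2 = numeric(cfg$classes))
}

initDecoderParams <- function(cfg, latentDim, emb = NULL) {
  H <- cfg$hidden; E <- cfg$embedDim; V <- cfg$vocabSize
  p <- list(
    dec_projHf = heInit(latentDim, H), dec_projHb = heInit(latentDim, H),
    dec_Emb = if (!is.null(emb)) emb else matrix(rnorm(V * E, 0, 0.1), V, E),
    dec_fwd_Wx = heInit(E, 4 * H, fanIn = E),
    dec_fwd_Wh = heInit(H, 4 * H, fanIn = H),
    dec_fwd_b = numeric(4 * H),
    dec_bwd_Wx = heInit(E, 4 * H, fanIn = E),
    dec_bwd_Wh = heInit(H, 4 * H, fanIn = H),
    dec_bwd_b = numeric(4 * H),
    dec_out_W = heInit(2 * H, V, fanIn = 2 * H),
    dec_out_b = numeric(V))
  if (cfg$projectCell) {
    p$dec_projCf <- heInit(latentDim, H)
    p$dec_projCb <- heInit(latentDim, H)
  }
  # forget-gate bias at 1 stabilizes early training
  p$dec_fwd_b[(H + 1):(2 * H)] <- 1
  p$dec_bwd_b[(H + 1):(2 * H)] <- 1
  p
}

# --- encoder forward / backward -------------------------------------------

# X: (B*H*W) x 1 activation matrix. Returns z (B x latentDim) and a cache
# for the backward pass. Dropout masks (train mode) are drawn from the
# current RNG stream.
encoderForwardCore <- function(params, X, B, cfg, train = FALSE) {
  layers <- archLayers(cfg$backbone)
  H <- cfg$inputSize; W <- cfg$inputSize
  act <- X - 0.5   # center [0,1] intensities; uncentered inputs condition
                   # the first layer poorly and slow early training
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      pad <- (l$k - 1L) %/% 2L
      cv <- .cpp_conv_relu_fw(act, params[[sprintf("enc_L%d_W", i)]],
                              params[[sprintf("enc_L%d_b", i)]],
                              H, W, B, l$k, l$k, pad)
      act <- cv$A
      caches[[i]] <- list(P = cv$P, Cin = ncol(cv$P) %/% (l$k * l$k),
                          H = H, W = W, A = act)
    } else if (l$type == "incept") {
      Cin <- ncol(act)
      outs <- list(); Ps <- list()
      for (j in seq_along(l$branches)) {
        br <- l$branches[[j]]
        pad <- (br[["k"]] - 1L) %/% 2L
        cv <- .cpp_conv_relu_fw(act, params[[sprintf("enc_L%d_b%d_W", i, j)]],
                                params[[sprintf("enc_L%d_b%d_b", i, j)]],
                                H, W, B, br[["k"]], br[["k"]], pad)
        outs[[j]] <- cv$A; Ps[[j]] <- cv$P
      }
      act <- do.call(cbind, outs)
      caches[[i]] <- list(P = Ps, A2 = outs, Cin = Cin, H = H, W = W,
                          A = act)
    } else {  # pool
      pl <- .cpp_maxpool2_fw(act, H, W, B)
      H <- H %/% 2L; W <- W %/% 2L
      act <- pl$out
      dm <- NULL
      # single dropout site at the deepest pooling stage: stacking dropout
      # on every stage starves a net this small of signal
      if (train && cfg$dropout > 0 && i == length(layers)) {
        dm <- matrix(dropMask(length(act), cfg$dropout), nrow(act), ncol(act))
        act <- act * dm
      }
      caches[[i]] <- list(idx = pl$idx, drop = dm, H = H, W = W)
    }
  }
  bIdx <- (seq_len(nrow(act)) - 1L) %/% (H * W)
  gap <- rowsum(act, bIdx) / (H * W)
  z <- addRowVec(gap %*% params$enc_fc_W, params$enc_fc_b)
  list(z = z, cache = list(layers = layers, caches = caches, gap = gap,
                           bIdx = bIdx, Hf = H, Wf = W, B = B))
}

# dz: B x latentDim. Returns weight gradients; optionally the gradient
# w.r.t. the input image (wantInput) and w.r.t. a named conv layer's
# post-ReLU activation (gradAtLayer, index into the layer list) for Grad-CAM.
encoderBackwardCore <- function(params, cache, dz, wantInput = FALSE,
                                gradAtLayer = NULL) {
  layers <- cache$layers
  caches <- cache$caches
  B <- cache$B
  g <- list()
  g$enc_fc_W <- crossprod(cache$gap, dz)
  g$enc_fc_b <- colSums(dz)
  dgap <- dz %*% t(params$enc_fc_W)
  Z <- cache$Hf * cache$Wf
  dact <- dgap[cache$bIdx + 1L, , drop = FALSE] / Z
  layerGrad <- NULL
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    cc <- caches[[i]]
    if (l$type == "pool") {
      if (!is.null(cc$drop)) dact <- dact * cc$drop
      dact <- .cpp_maxpool2_bw(dact, cc$idx, cc$H * 2L, cc$W * 2L, B)
    } else if (l$type == "conv") {
      if (!is.null(gradAtLayer) && gradAtLayer == i) {
        layerGrad <- dact
        if (!wantInput) break
      }
      pad <- (l$k - 1L) %/% 2L
      r <- .cpp_conv_relu_bw(cc$P, params[[sprintf("enc_L%d_W", i)]],
                             cc$A, dact, cc$H, cc$W, cc$Cin, B,
                             l$k, l$k, pad)
      g[[sprintf("enc_L%d_W", i)]] <- r$dW
      g[[sprintf("enc_L%d_b", i)]] <- as.numeric(r$db)
      dact <- r$dX
    } else {  # incept
      if (!is.null(gradAtLayer) && gradAtLayer == i) {
        layerGrad <- dact
        if (!wantInput) break
      }
      off <- 0L
      dsum <- NULL
      for (j in seq_along(l$branches)) {
        br <- l$branches[[j]]
        Cb <- br[["Cout"]]
        pad <- (br[["k"]] - 1L) %/% 2L
        r <- .cpp_conv_relu_bw(cc$P[[j]],
                               params[[sprintf("enc_L%d_b%d_W", i, j)]],
                               cc$A2[[j]],
                               dact[, (off + 1L):(off + Cb), drop = FALSE],
                               cc$H, cc$W, cc$Cin, B, br[["k"]], br[["k"]],
                               pad)
        off <- off + Cb
        g[[sprintf("enc_L%d_b%d_W", i, j)]] <- r$dW
        g[[sprintf("enc_L%d_b%d_b", i, j)]] <- as.numeric(r$db)
        dsum <- if (is.null(dsum)) r$dX else dsum + r$dX
      }
      dact <- dsum
    }
  }
  list(grads = g, dInput = if (wantInput) dact else NULL,
       layerGrad = layerGrad)
}

# --- classifier ------------------------------------------------------------

classifierForwardCore <- function(params, z) {
  A1 <- addRowVec(z %*% params$cls_W1, params$cls_b1)
  H1 <- A1 * (A1 > 0)
  logits <- addRowVec(H1 %*% params$cls_W2, params$cls_b2)
  list(logits = logits, cache = list(z = z, H1 = H1, relu = A1 > 0))
}

classifierBackwardCore <- function(params, cache, dlogits) {
  g <- list(cls_W2 = crossprod(cache$H1, dlogits),
            cls_b2 = colSums(dlogits))
  dH1 <- (dlogits %*% t(params$cls_W2)) * cache$relu
  g$cls_W1 <- crossprod(cache$z, dH1)
  g$cls_b1 <- colSums(dH1)
  list(grads = g, dz = dH1 %*% t(params$cls_W1))
}

# --- decoder ---------------------------------------------------------------

cube2mat <- function(a) {   # B x H x T -> (B*T) x H, row index b + B*t
  d <- dim(a)
  m <- aperm(a, c(1, 3, 2))
  dim(m) <- c(d[1] * d[3], d[2])
  m
}
mat2cube <- function(m, B, Tn) {  # inverse of cube2mat
  Hn <- ncol(m)
  a <- array(m, c(B, Tn, Hn))
  aperm(a, c(1, 3, 2))
}

# teacherIds: B x T matrix of 0-based token ids; lengths: true lengths per
# sample (PAD beyond). The backward-direction LSTM runs on each sample's
# sequence reversed within its true length, so trailing PAD never feeds the
# states at real positions.
decoderForwardCore <- function(params, z, teacherIds, lengths, cfg,
                               train = FALSE) {
  B <- nrow(teacherIds); Tn <- ncol(teacherIds)
  Hn <- cfg$hidden; E <- cfg$embedDim; V <- cfg$vocabSize
  flat <- as.vector(teacherIds)          # rows b + B*t
  M <- params$dec_Emb[flat + 1L, , drop = FALSE]
  dmEmb <- NULL
  if (train && cfg$dropout > 0) {
    # token-granular input dropout: whole embeddings are blanked, making
    # restoration cloze-like so the latent code must carry report content
    # (elementwise dropout leaves token identity recoverable)
    dmEmb <- dropMask(nrow(M), cfg$dropout)
    M <- M * dmEmb
  }
  # per-sample reversal map (involution), 1-based step indices
  tmat <- matrix(rep(seq_len(Tn), each = B), B, Tn)
  L <- matrix(rep(lengths, Tn), B, Tn)
  revT <- ifelse(tmat <= L, L + 1L - tmat, tmat)
  rowRev <- as.vector(rep(seq_len(B), Tn) + B * (revT - 1L))
  Mrev <- M[rowRev, , drop = FALSE]

  h0f <- z %*% params$dec_projHf
  h0b <- z %*% params$dec_projHb
  c0f <- if (cfg$projectCell) z %*% params$dec_projCf else matrix(0, B, Hn)
  c0b <- if (cfg$projectCell) z %*% params$dec_projCb else matrix(0, B, Hn)

  fw <- .cpp_lstm_fw(mat2cube(M, B, Tn), h0f, c0f,
                     params$dec_fwd_Wx, params$dec_fwd_Wh, params$dec_fwd_b)
  bw <- .cpp_lstm_fw(mat2cube(Mrev, B, Tn), h0b, c0b,
                     params$dec_bwd_Wx, params$dec_bwd_Wh, params$dec_bwd_b)
  Hf <- cube2mat(fw$H)                   # (B*T) x H
  HbRev <- cube2mat(bw$H)
  Hb <- HbRev[rowRev, , drop = FALSE]    # align to original positions
  Hcat <- cbind(Hf, Hb)
  dmH <- NULL
  if (train && cfg$dropout > 0) {
    dmH <- matrix(dropMask(length(Hcat), cfg$dropout), nrow(Hcat), ncol(Hcat))
    Hcat <- Hcat * dmH
  }
  logits <- addRowVec(Hcat %*% params$dec_out_W, params$dec_out_b)
  probs <- softmaxRows(logits)
  list(probs = probs,                    # (B*T) x V, rows b + B*t
       cache = list(B = B, Tn = Tn, flat = flat, rowRev = rowRev,
                    M = M, Mrev = Mrev, dmEmb = dmEmb, dmH = dmH,
                    h0f = h0f, h0b = h0b, c0f = c0f, c0b = c0b,
                    fw = fw, bw = bw, Hcat = Hcat, z = z))
}

decoderBackwardCore <- function(params, cache, dlogits, cfg) {
  B <- cache$B; Tn <- cache$Tn; Hn <- cfg$hidden; V <- cfg$vocabSize
  g <- list(dec_out_W = crossprod(cache$Hcat, dlogits),
            dec_out_b = colSums(dlogits))
  dHcat <- dlogits %*% t(params$dec_out_W)
  if (!is.null(cache$dmH)) dHcat <- dHcat * cache$dmH
  dHf <- dHcat[, seq_len(Hn), drop = FALSE]
  dHb <- dHcat[, Hn + seq_len(Hn), drop = FALSE]
  dHbRev <- dHb[cache$rowRev, , drop = FALSE]

  Xf <- mat2cube(cache$M, B, Tn)
  Xb <- mat2cube(cache$Mrev, B, Tn)
  bwF <- .cpp_lstm_bw(Xf, cache$h0f, cache$c0f,
                      params$dec_fwd_Wx, params$dec_fwd_Wh,
                      cache$fw$H, cache$fw$C, cache$fw$G, cache$fw$TanhC,
                      mat2cube(dHf, B, Tn))
  bwB <- .cpp_lstm_bw(Xb, cache$h0b, cache$c0b,
                      params$dec_bwd_Wx, params$dec_bwd_Wh,
                      cache$bw$H, cache$bw$C, cache$bw$G, cache$bw$TanhC,
                      mat2cube(dHbRev, B, Tn))
  g$dec_fwd_Wx <- bwF$dWx; g$dec_fwd_Wh <- bwF$dWh; g$dec_fwd_b <- as.numeric(bwF$db)
  g$dec_bwd_Wx <- bwB$dWx; g$dec_bwd_Wh <- bwB$dWh; g$dec_bwd_b <- as.numeric(bwB$db)

  dM <- cube2mat(bwF$dX)
  dMrevAligned <- cube2mat(bwB$dX)[cache$rowRev, , drop = FALSE]
  dM <- dM + dMrevAligned
  if (!is.null(cache$dmEmb)) dM <- dM * cache$dmEmb
  if (cfg$embedTrain) {
    agg <- rowsum(dM, cache$flat)
    dEmb <- matrix(0, V, cfg$embedDim)
    dEmb[as.integer(rownames(agg)) + 1L, ] <- agg
    g$dec_Emb <- dEmb
  }
  dz <- bwF$dh0 %*% t(params$dec_projHf) + bwB$dh0 %*% t(params$dec_projHb)
  g$dec_projHf <- crossprod(cache$z, bwF$dh0)
  g$dec_projHb <- crossprod(cache$z, bwB$dh0)
  if (cfg$projectCell) {
    dz <- dz + bwF$dc0 %*% t(params$dec_projCf) +
               bwB$dc0 %*% t(params$dec_projCb)
    g$dec_projCf <- crossprod(cache$z, bwF$dc0)
    g$dec_projCb <- crossprod(cache$z, bwB$dc0)
  }
  list(grads = g, dz = dz)
}

# --- Adam ------------------------------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    if (is.null(params[[nm]])) next
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
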
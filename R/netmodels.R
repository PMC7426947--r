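## Public model surface: encoder / decoder / classifier forward passes on a
## shared latent code, image-only prediction, checkpoint I/O.

# Canonicalize image input to the internal (B*H*W) x 1 activation matrix.
# Accepts a single H x W matrix, a list of H x W matrices, or an H x W x B
# array. Intensities are expected in \[0,1\].
imagesToMat <- function(images, inputSize) {
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 3L)
    images <- lapply(seq_len(dim(images)[3]), function(b) images[, , b])
  B <- length(images)
  for (im in images)
    if (!all(dim(im) == inputSize))
      stop(sprintf("images must be %d x %d", inputSize, inputSize))
  X <- matrix(unlist(images, use.names = FALSE), ncol = 1L)
  list(X = X, B = B)
}

#' Encode images into the shared latent representation
#'
#' Pure function of the image in eval mode (`trainMode = FALSE`): dropout is
#' only active during training.
#'
#' @param params flat named parameter list (e.g. `model@params`).
#' @param images a single H x W matrix, list of matrices, or H x W x B
#'   array, intensities in \[0,1\], H = W = `cfg$inputSize`.
#' @param cfg an [encoderConfig()].
#' @param trainMode activate dropout (draws masks from the current RNG).
#' @return B x latentDim matrix of latent codes.
#' @export
encoderForward <- function(params, images, cfg, trainMode = FALSE) {
  im <- imagesToMat(images, cfg$inputSize)
  encoderForwardCore(params, im$X, im$B, cfg, train = trainMode)$z
}

#' Decode latent codes into per-step vocabulary distributions
#'
#' Teacher-forced bidirectional LSTM decoder: the latent code is linearly
#' projected to the initial hidden (and, by default, cell) states of both
#' directions; the full target token sequence is the step input. Every
#' output row is a probability distribution over the vocabulary.
#'
#' @param params flat named parameter list.
#' @param z B x latentDim latent codes.
#' @param teacherIds B x T matrix of 0-based token ids (PAD = 0 beyond each
#'   report's length), T <= `cfg$steps`.
#' @param lengths integer vector of true report lengths (default: all T).
#' @param cfg a [decoderConfig()].
#' @param trainMode activate dropout.
#' @return B x T x V array of per-step vocabulary distributions.
#' @export
decoderForward <- function(params, z, teacherIds, lengths = NULL, cfg,
                           trainMode = FALSE) {
  if (is.null(dim(teacherIds))) teacherIds <- matrix(teacherIds, 1)
  if (ncol(params$dec_Emb) != cfg$embedDim ||
      nrow(params$dec_Emb) != cfg$vocabSize)
    stop("vocabulary/embedding size mismatch between params and config")
  if (ncol(z) != nrow(params$dec_projHf))
    stop("latent dimension mismatch")
  if (is.null(lengths)) lengths <- rep(ncol(teacherIds), nrow(teacherIds))
  out <- decoderForwardCore(params, z, teacherIds, as.integer(lengths), cfg,
                            train = trainMode)
  B <- nrow(teacherIds); Tn <- ncol(teacherIds)
  array(out$probs, c(B, Tn, cfg$vocabSize))  # rows are b + B*t
}

#' Classify latent codes
#'
#' Two fully-connected layers (ReLU hidden), returning raw logits; no
#' softmax inside.
#'
#' @param params flat named parameter list.
#' @param z B x latentDim latent codes.
#' @return B x K logit matrix.
#' @export
classifierForward <- function(params, z) {
  stopifnot(all(is.finite(z)))
  classifierForwardCore(params, z)$logits
}

#' Predict class probabilities for a single image
#'
#' Image-only inference: encoder then classifier then softmax. The report
#' decoder is never consulted.
#'
#' @param model a trained [FractureNet-class].
#' @param image H x W matrix in \[0,1\].
#' @return named probability vector over [aoClasses()] (sums to 1).
#' @export
predictImage <- function(model, image) {
  if (!length(model@params)) stop("model has no trained parameters")
  z <- encoderForward(model@params, image, model@configs$encoder)
  logits <- classifierForward(model@params, z)
  p <- softmaxRows(logits)[1, ]
  setNames(p, aoClasses()[seq_along(p)])
}

#' Latent codes for a batch of images under a trained model
#'
#' @param model a [FractureNet-class].
#' @param images images as accepted by [encoderForward()].
#' @return B x latentDim matrix.
#' @export
latentCodes <- function(model, images) {
  if (!length(model@params)) stop("model has no trained parameters")
  encoderForward(model@params, images, model@configs$encoder)
}

#' Save / load a model checkpoint
#'
#' Single-file binary format: one JSON header line (configs, regime, seed,
#' format version) followed by the serialized parameter payload.
#'
#' @param model a [FractureNet-class].
#' @param path checkpoint file path.
#' @return `saveCheckpoint` returns `path` invisibly; `readCheckpoint`
#'   returns the restored [FractureNet-class].
#' @export
saveCheckpoint <- function(model, path) {
  header <- jsonlite::toJSON(
    list(format = "hipfrax-checkpoint-1", regime = model@regime,
         seed = model@seed, configs = model@configs),
    auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(as.character(header), con)
  payload <- list(params = model@params, log = model@log,
                  vocab = if (is.null(model@vocab)) NULL else list(
                    tokens = model@vocab@tokens,
                    frequencies = model@vocab@frequencies,
                    specials = model@vocab@specials))
  writeBin(serialize(payload, NULL), con)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
readCheckpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint '%s' not found", path))
  con <- file(path, "rb")
  on.exit(close(con))
  header <- jsonlite::fromJSON(readLines(con, n = 1L))
  raw <- readBin(con, "raw", n = file.size(path))
  payload <- unserialize(raw)
  vocab <- NULL
  if (!is.null(payload$vocab))
    vocab <- new("ReportVocabulary", tokens = payload$vocab$tokens,
                 frequencies = payload$vocab$frequencies,
                 specials = payload$vocab$specials)
  cfgs <- header$configs
  # jsonlite round-trips scalars fine; restore integer-ish fields
  new("FractureNet", params = payload$params, configs = cfgs,
      vocab = vocab, regime = header$regime,
      seed = as.integer(header$seed), log = payload$log)
}
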
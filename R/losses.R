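## Scalar loss functions. Reductions: sum over classes/steps, mean over the
## batch. Probabilities are clamped at EPS inside logs so a zero probability
## at a target index yields a large finite loss rather than Inf.

EPS_LOG <- 1e-12

asBatch <- function(x) {
  if (is.null(dim(x))) matrix(x, 1) else x
}

#' Report-reconstruction cross-entropy (encoder-decoder loss)
#'
#' \eqn{-\sum_i L^{dec}_i \log Y^{dec}_i} summed over the masked (non-PAD)
#' steps of each report and averaged over the batch. PAD steps contribute
#' exactly zero.
#'
#' @param Ydec decoder output distributions: `T x V` matrix or `B x T x V`
#'   array, each step row a probability distribution.
#' @param Ldec one-hot targets, same shape.
#' @param mask step mask (1 = real token): length-T vector or `B x T` matrix.
#'   Default all-ones.
#' @return nonnegative scalar.
#' @export
encoderDecoderLoss <- function(Ydec, Ldec, mask = NULL) {
  if (length(dim(Ydec)) == 2L) {
    Ydec <- array(Ydec, c(1, dim(Ydec)))
    Ldec <- array(Ldec, c(1, dim(Ldec)))
  }
  stopifnot(identical(dim(Ydec), dim(Ldec)))
  B <- dim(Ydec)[1]; Tn <- dim(Ydec)[2]
  if (is.null(mask)) mask <- matrix(1, B, Tn)
  mask <- asBatch(mask)
  # per-step CE at the target index
  ce <- -log(pmax(apply(Ydec * Ldec, c(1, 2), sum), EPS_LOG))
  sum(ce * mask) / B
}

#' Classification cross-entropy
#'
#' \eqn{-\sum_i L^{cls}_i \log Y^{cls}_i} per sample, averaged over the
#' batch.
#'
#' @param Ycls class probability vector or `B x K` matrix of distributions.
#' @param Lcls one-hot target, same shape.
#' @return nonnegative scalar.
#' @export
classifierLoss <- function(Ycls, Lcls) {
  Y <- asBatch(Ycls); L <- asBatch(Lcls)
  stopifnot(identical(dim(Y), dim(L)))
  mean(-log(pmax(rowSums(Y * L), EPS_LOG)))
}

#' Focal loss for imbalanced classification
#'
#' \eqn{-\alpha_t (1 - p_t)^\gamma \log p_t} with \eqn{p_t} the predicted
#' probability at the target class, averaged over the batch. With
#' `gamma = 0` and unit `alpha` this reduces exactly to [classifierLoss()].
#'
#' @inheritParams classifierLoss
#' @param gamma focusing parameter (>= 0; default 2).
#' @param alpha per-class weight vector (length K) or `NULL` for unweighted.
#' @return nonnegative scalar.
#' @export
focalLoss <- function(Ycls, Lcls, gamma = 2, alpha = NULL) {
  if (gamma < 0) stop("gamma must be >= 0")
  Y <- asBatch(Ycls); L <- asBatch(Lcls)
  stopifnot(identical(dim(Y), dim(L)))
  pt <- pmax(rowSums(Y * L), EPS_LOG)
  at <- if (is.null(alpha)) 1 else {
    if (any(alpha < 0)) stop("alpha entries must be >= 0")
    as.numeric(L %*% alpha)
  }
  mean(-at * (1 - pt)^gamma * log(pt))
}

#' Joint training loss
#'
#' \eqn{L = L_{cls} + \lambda L_{encoder\mbox{-}decoder}}: the classification
#' loss plus the \eqn{\lambda}-weighted report-reconstruction loss.
#'
#' @param lCls classification loss (scalar).
#' @param lEncDec encoder-decoder loss (scalar).
#' @param lambda nonnegative reconstruction weight (default 0.5).
#' @return scalar.
#' @export
jointLoss <- function(lCls, lEncDec, lambda = 0.5) {
  if (lambda < 0) stop("lambda must be >= 0")
  stopifnot(is.finite(lCls), is.finite(lEncDec))
  lCls + lambda * lEncDec
}

# Per-class focal alpha default: inverse class frequency normalized to mean 1.
inverseFrequencyAlpha <- function(labels, classes = aoClasses()) {
  n <- table(factor(labels, levels = classes))
  w <- ifelse(n > 0, 1 / pmax(as.numeric(n), 1), 0)
  w <- w / mean(w[n > 0])
  setNames(as.numeric(w), classes)
}
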
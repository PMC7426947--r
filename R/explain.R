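## Grad-CAM class-discriminative saliency: gradients of the pre-softmax
## class score w.r.t. a convolutional layer's feature maps are global-
## average-pooled into neuron-importance weights, the weighted feature-map
## combination is ReLU-rectified into a coarse heat map, and the map is
## bilinearly upsampled over the input image for overlays.

#' Neuron-importance weights from feature-map gradients
#'
#' Global average pooling of the class-score gradients:
#' \eqn{\alpha_k = \frac{1}{Z}\sum_i\sum_j \partial y^c / \partial A^k_{ij}}
#' with Z = u*v.
#'
#' @param gradients u x v x k array of gradients of the class score w.r.t.
#'   each feature map.
#' @return numeric vector of k importance weights.
#' @export
neuronImportance <- function(gradients) {
  if (length(dim(gradients)) != 3L || any(dim(gradients) == 0L))
    stop("gradients must be a non-empty u x v x k array")
  apply(gradients, 3, mean)
}

#' Grad-CAM heat map from feature maps and importance weights
#'
#' \eqn{ReLU(\sum_k \alpha_k A^k)}: only features with positive influence on
#' the target class are retained. The map has the feature-map resolution.
#'
#' @param A u x v x k array of feature maps.
#' @param alpha length-k importance weights.
#' @return u x v nonnegative matrix.
#' @export
gradcamMap <- function(A, alpha) {
  d <- dim(A)
  if (length(d) != 3L || d[3] != length(alpha))
    stop("feature-map stack and alpha shapes are inconsistent")
  m <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) m <- m + alpha[k] * A[, , k]
  pmax(m, 0)
}

upsampleBilinear <- function(m, size) {
  u <- nrow(m); v <- ncol(m)
  sy <- pmin(pmax((seq_len(size) - 0.5) * u / size + 0.5, 1), u)
  sx <- pmin(pmax((seq_len(size) - 0.5) * v / size + 0.5, 1), v)
  y0 <- pmin(floor(sy), u - 1L); x0 <- pmin(floor(sx), v - 1L)
  fy <- sy - y0; fx <- sx - x0
  m00 <- m[y0, x0, drop = FALSE]; m10 <- m[y0 + 1, x0, drop = FALSE]
  m01 <- m[y0, x0 + 1, drop = FALSE]; m11 <- m[y0 + 1, x0 + 1, drop = FALSE]
  W00 <- outer(1 - fy, 1 - fx); W10 <- outer(fy, 1 - fx)
  W01 <- outer(1 - fy, fx);     W11 <- outer(fy, fx)
  m00 * W00 + m10 * W10 + m01 * W01 + m11 * W11
}

# indices of conv/incept layers in a backbone's layer list
convLayerIndices <- function(backbone) {
  layers <- archLayers(backbone)
  which(vapply(layers, function(l) l$type %in% c("conv", "incept"),
               logical(1)))
}

#' Names of the spatial layers available for Grad-CAM
#'
#' @param model a [FractureNet-class].
#' @return character vector of layer names (`"L<i>"` in forward order); the
#'   last one is the default Grad-CAM target.
#' @export
convLayers <- function(model) {
  paste0("L", convLayerIndices(model@configs$encoder$backbone))
}

#' Grad-CAM explanation for one image
#'
#' Composes the eval-mode forward pass, the gradient of the pre-softmax
#' class score through classifier and encoder down to the target
#' convolutional layer's feature maps, neuron-importance pooling and the
#' ReLU-rectified weighted map. The overlay is the map bilinearly upsampled
#' to the image size and scaled to \[0,1\] by its maximum (all-zero maps stay
#' all-zero).
#'
#' @param model a trained [FractureNet-class].
#' @param image H x W matrix in \[0,1\].
#' @param targetClass class name (one of [aoClasses()]) or 1-based index.
#' @param layer layer name from [convLayers()] (default: the last
#'   convolutional layer).
#' @param score differentiate the pre-softmax class score (default) or the
#'   post-softmax probability (for comparison; the two differ in general).
#' @return list with `map` (u x v, nonnegative), `overlay` (image-sized,
#'   in \[0,1\]), `alpha`, `class`, `layer`.
#' @export
explainImage <- function(model, image, targetClass, layer = NULL,
                         score = c("pre-softmax", "post-softmax")) {
  score <- match.arg(score)
  if (!length(model@params)) stop("model has no trained parameters")
  enc <- model@configs$encoder
  cls <- if (is.character(targetClass)) match(targetClass, aoClasses())
         else as.integer(targetClass)
  if (is.na(cls)) stop("unknown target class")
  idxAll <- convLayerIndices(enc$backbone)
  li <- if (is.null(layer)) idxAll[length(idxAll)] else {
    v <- as.integer(sub("^L", "", layer))
    if (!v %in% idxAll) stop(sprintf("'%s' is not a spatial layer", layer))
    v
  }
  im <- imagesToMat(image, enc$inputSize)
  ef <- encoderForwardCore(model@params, im$X, 1L, enc, train = FALSE)
  cf <- classifierForwardCore(model@params, ef$z)
  K <- ncol(cf$logits)
  dlogits <- matrix(0, 1, K)
  if (score == "pre-softmax") {
    dlogits[1, cls] <- 1
  } else {
    p <- softmaxRows(cf$logits)[1, ]
    dlogits[1, ] <- p[cls] * ((seq_len(K) == cls) - p)
  }
  cb <- classifierBackwardCore(model@params, cf$cache, dlogits)
  eb <- encoderBackwardCore(model@params, ef$cache, cb$dz,
                            gradAtLayer = li)
  cc <- ef$cache$caches[[li]]
  u <- cc$H; v <- cc$W
  Amat <- if (is.list(cc$A)) do.call(cbind, cc$A) else cc$A
  k <- ncol(Amat)
  A <- array(Amat, c(u, v, k))
  G <- array(eb$layerGrad, c(u, v, k))
  alpha <- neuronImportance(G)
  map <- gradcamMap(A, alpha)
  ov <- upsampleBilinear(map, enc$inputSize)
  mx <- max(ov)
  if (mx > 0) ov <- ov / mx
  list(map = map, overlay = ov, alpha = alpha,
       class = aoClasses()[cls], layer = paste0("L", li))
}

#' Saliency mass inside a ground-truth fracture mask
#'
#' Lesion-hit statistic for synthetic phantoms: the fraction of total
#' saliency falling inside the fracture mask, and the mask's area fraction
#' (the mass a uniform map would place there). A converged model attending
#' to the lesion yields `inMask` well above `maskArea`.
#'
#' @param overlay image-sized nonnegative saliency map.
#' @param mask binary matrix of the same size.
#' @return named vector `c(inMask, maskArea)`.
#' @export
saliencyMaskOverlap <- function(overlay, mask) {
  stopifnot(all(dim(overlay) == dim(mask)))
  tot <- sum(overlay)
  c(inMask = if (tot > 0) sum(overlay[mask > 0]) / tot else 0,
    maskArea = mean(mask > 0))
}
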
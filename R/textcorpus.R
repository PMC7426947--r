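## Report corpus handling: tokenization, frequency-truncated vocabulary,
## one-hot sequence encoding, co-occurrence counts and GloVe-style embeddings.

SPECIALS <- c(pad = "<pad>", start = "<s>", end = "</s>", unk = "<unk>")

#' Tokenize a radiology report
#'
#' Lowercases, splits on whitespace and strips leading/trailing punctuation
#' from each token. Alphanumeric class codes such as "a1" are kept intact.
#' Deterministic by construction.
#'
#' @param text a UTF-8 report string.
#' @return character vector of tokens.
#' @export
#' @examples
#' tokenizeReport("Fracture of left femoral neck.")
tokenizeReport <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("empty report: text must be non-empty after whitespace stripping")
  toks <- strsplit(trimws(tolower(text)), "\\s+")[[1]]
  toks <- gsub("^[^a-z0-9]+|[^a-z0-9]+$", "", toks)
  toks[nzchar(toks)]
}

#' Build a frequency-truncated vocabulary from a token corpus
#'
#' Keeps the `maxSize` most frequent tokens (frequency ties broken
#' lexicographically, so the result is invariant to corpus order) and
#' prepends the special tokens `<pad>`, `<s>`, `</s>`, `<unk>`; `<pad>` is
#' always id 0.
#'
#' @param corpus list of token vectors (one per report).
#' @param maxSize maximum number of non-special tokens to keep (default 300,
#'   the frequency cap used for the report corpus).
#' @return a [ReportVocabulary-class].
#' @export
buildVocabulary <- function(corpus, maxSize = 300L) {
  if (!length(corpus) || !sum(lengths(corpus)))
    stop("empty corpus: cannot build a vocabulary")
  if (maxSize < 1L) stop("maxSize must be >= 1")
  tab <- table(unlist(corpus, use.names = FALSE))
  freq <- as.integer(tab)
  names(freq) <- names(tab)
  ord <- order(-freq, names(freq), method = "radix")
  keep <- head(ord, maxSize)
  kept <- freq[keep]
  new("ReportVocabulary",
      tokens = c(unname(SPECIALS), names(kept)),
      frequencies = kept,
      specials = SPECIALS)
}

#' Map tokens to integer ids
#'
#' @param vocab a [ReportVocabulary-class].
#' @param tokens character vector of tokens.
#' @return integer vector of 0-based ids; out-of-vocabulary tokens map to the
#'   `<unk>` id.
#' @export
tokenIds <- function(vocab, tokens) {
  id <- match(tokens, vocab@tokens) - 1L
  id[is.na(id)] <- match(SPECIALS[["unk"]], vocab@tokens) - 1L
  id
}

#' @rdname tokenIds
#' @param ids integer vector of 0-based ids.
#' @export
idTokens <- function(vocab, ids) {
  stopifnot(all(ids >= 0L), all(ids < vocabSize(vocab)))
  vocab@tokens[ids + 1L]
}

#' Tokenize a report against a vocabulary
#'
#' @inheritParams tokenIds
#' @param text report string.
#' @param maxLen maximum report length in tokens (default 40, the corpus
#'   maximum); longer reports are truncated with a warning.
#' @return list with `tokens`, 0-based `ids` and pre-padding `length`.
#' @export
tokenizedReport <- function(text, vocab, maxLen = 40L) {
  toks <- tokenizeReport(text)
  if (length(toks) > maxLen) {
    warning(sprintf("report truncated from %d to %d tokens",
                    length(toks), maxLen))
    toks <- toks[seq_len(maxLen)]
  }
  list(tokens = toks, ids = tokenIds(vocab, toks), length = length(toks))
}

#' One-hot encode a tokenized report to fixed length
#'
#' Produces the `maxLen` x V binary matrix fed to the report decoder: row i
#' is the one-hot of token i, rows beyond the report length are `<pad>`
#' one-hots, and the mask marks real tokens.
#'
#' @param report list as returned by [tokenizedReport()].
#' @param vocab a [ReportVocabulary-class].
#' @param maxLen sequence length (default 40).
#' @return list with `matrix` (maxLen x V), `mask` (length maxLen, 1 = real
#'   token), `ids` and `length`.
#' @export
encodeOneHot <- function(report, vocab, maxLen = 40L) {
  len <- report$length
  ids <- report$ids
  if (len > maxLen) {
    warning(sprintf("report truncated from %d to %d tokens", len, maxLen))
    ids <- ids[seq_len(maxLen)]
    len <- maxLen
  }
  V <- vocabSize(vocab)
  padId <- 0L
  full <- c(ids, rep(padId, maxLen - len))
  m <- matrix(0, maxLen, V)
  m[cbind(seq_len(maxLen), full + 1L)] <- 1
  list(matrix = m, mask = as.numeric(seq_len(maxLen) <= len),
       ids = ids, length = len)
}

#' Global word-to-word co-occurrence counts
#'
#' Counts, over the whole corpus, how often token j occurs within `window`
#' positions of token i (both directions; distance 0, i.e. a token with
#' itself at the same position, never counts). Out-of-vocabulary tokens are
#' dropped before counting. With `weighting = "harmonic"` a pair at distance
#' d contributes 1/d, the weighting used by the GloVe construction.
#'
#' @param corpus list of token vectors.
#' @param vocab a [ReportVocabulary-class].
#' @param window context window size (>= 1).
#' @param weighting `"uniform"` or `"harmonic"` (1/distance).
#' @return V x V numeric matrix of (weighted) counts, V = `vocabSize(vocab)`;
#'   attributes `window` and `weighting`.
#' @export
buildCooccurrence <- function(corpus, vocab, window = 5L,
                              weighting = c("uniform", "harmonic")) {
  if (window < 1L) stop("window must be >= 1")
  weighting <- match.arg(weighting)
  V <- vocabSize(vocab)
  counts <- matrix(0, V, V,
                   dimnames = list(vocab@tokens, vocab@tokens))
  unkId <- match(SPECIALS[["unk"]], vocab@tokens) - 1L
  for (toks in corpus) {
    ids <- match(toks, vocab@tokens) - 1L  # OOV -> NA -> dropped
    ids <- ids[!is.na(ids) & ids != unkId]
    n <- length(ids)
    if (n < 2L) next
    for (d in seq_len(min(window, n - 1L))) {
      w <- if (weighting == "harmonic") 1 / d else 1
      i <- ids[seq_len(n - d)] + 1L
      j <- ids[seq_len(n - d) + d] + 1L
      for (k in seq_along(i)) {
        counts[i[k], j[k]] <- counts[i[k], j[k]] + w
        counts[j[k], i[k]] <- counts[j[k], i[k]] + w
      }
    }
  }
  structure(counts, window = window, weighting = weighting)
}

# GloVe weighted-least-squares objective over the nonzero cells:
#   J = sum f(X_ij) (w_i.wt_j + b_i + bt_j - log X_ij)^2,
# f(x) = (x/xmax)^alpha capped at 1.
gloveObjective <- function(counts, W, Wt, b, bt, xmax, alpha) {
  nz <- counts > 0
  f <- pmin((counts / xmax)^alpha, 1)
  err <- (W %*% t(Wt) + outer(b, rep(1, length(bt))) +
          outer(rep(1, length(b)), bt) - suppressWarnings(log(counts)))
  err[!nz] <- 0
  sum(f[nz] * err[nz]^2)
}

#' Fit GloVe-style word embeddings on a co-occurrence matrix
#'
#' Minimizes the weighted least-squares objective
#' \eqn{\sum_{X_{ij}>0} f(X_{ij}) (w_i^\top \tilde w_j + b_i + \tilde b_j -
#' \log X_{ij})^2} with \eqn{f(x) = \min((x/x_{max})^{0.75}, 1)} by
#' full-batch gradient descent with backtracking (the step is halved whenever
#' the objective would increase), which makes the objective non-increasing
#' across epochs and the fit deterministic under a fixed seed. The returned
#' vectors are \eqn{w + \tilde w}.
#'
#' @param counts V x V co-occurrence matrix from [buildCooccurrence()].
#' @param d embedding dimension (default 128).
#' @param epochs number of full-batch epochs (default 100).
#' @param seed RNG seed for the initialization.
#' @param xmax,alpha weighting-function parameters (defaults 100 and 0.75).
#' @param lr initial learning rate.
#' @return list with `vectors` (V x d matrix), the per-epoch `objective`
#'   trace, and the `seed`/`d` used.
#' @export
fitGlove <- function(counts, d = 128L, epochs = 100L, seed = 1L,
                     xmax = 100, alpha = 0.75, lr = 0.05) {
  V <- nrow(counts)
  nz <- counts > 0
  if (!any(nz)) stop("all-zero co-occurrence matrix: nothing to fit")
  f <- pmin((counts / xmax)^alpha, 1)
  f[!nz] <- 0
  logX <- matrix(0, V, V)
  logX[nz] <- log(counts[nz])
  init <- withr::with_seed(seed, list(
    W = matrix(runif(V * d, -0.5, 0.5) / d, V, d),
    Wt = matrix(runif(V * d, -0.5, 0.5) / d, V, d),
    b = runif(V, -0.5, 0.5) / d,
    bt = runif(V, -0.5, 0.5) / d))
  W <- init$W; Wt <- init$Wt; b <- init$b; bt <- init$bt
  obj <- function(W, Wt, b, bt) {
    err <- (W %*% t(Wt) + outer(b, rep(1, V)) + outer(rep(1, V), bt) - logX)
    err[!nz] <- 0
    sum(f * err^2)
  }
  trace <- numeric(epochs)
  J <- obj(W, Wt, b, bt)
  for (ep in seq_len(epochs)) {
    err <- (W %*% t(Wt) + outer(b, rep(1, V)) + outer(rep(1, V), bt) - logX)
    err[!nz] <- 0
    FE <- f * err
    gW <- 2 * FE %*% Wt
    gWt <- 2 * t(FE) %*% W
    gb <- 2 * rowSums(FE)
    gbt <- 2 * colSums(FE)
    repeat {
      Wn <- W - lr * gW; Wtn <- Wt - lr * gWt
      bn <- b - lr * gb; btn <- bt - lr * gbt
      Jn <- obj(Wn, Wtn, bn, btn)
      if (Jn <= J + 1e-12 || lr < 1e-12) break
      lr <- lr / 2
    }
    W <- Wn; Wt <- Wtn; b <- bn; bt <- btn; J <- Jn
    trace[ep] <- J
  }
  vectors <- W + Wt
  rownames(vectors) <- rownames(counts)
  list(vectors = vectors, objective = trace, seed = seed, d = d)
}

#' Persist and restore a vocabulary as JSON
#'
#' @param vocab a [ReportVocabulary-class].
#' @param path file path.
#' @return `readVocabulary` returns a [ReportVocabulary-class];
#'   `saveVocabulary` returns `path` invisibly.
#' @export
saveVocabulary <- function(vocab, path) {
  nonspecial <- vocab@tokens[-seq_along(vocab@specials)]
  obj <- list(
    specials = as.list(vocab@specials),
    tokens = data.frame(token = vocab@tokens,
                        id = seq_along(vocab@tokens) - 1L,
                        frequency = c(rep(NA_integer_, length(vocab@specials)),
                                      unname(vocab@frequencies[nonspecial]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveVocabulary
#' @export
readVocabulary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tok <- obj$tokens
  nonspecial <- !is.na(tok$frequency)
  new("ReportVocabulary",
      tokens = tok$token,
      frequencies = setNames(as.integer(tok$frequency[nonspecial]),
                             tok$token[nonspecial]),
      specials = unlist(obj$specials))
}

#' Persist embeddings as a flat binary array with a JSON sidecar
#'
#' @param emb list returned by [fitGlove()].
#' @param path path for the binary array; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly; `readEmbeddings(path)` restores the matrix.
#' @export
saveEmbeddings <- function(emb, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(emb$vectors), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(V = nrow(emb$vectors), d = ncol(emb$vectors), seed = emb$seed,
         tokens = rownames(emb$vectors)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveEmbeddings
#' @export
readEmbeddings <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = meta$V * meta$d, size = 8,
               endian = "little")
  matrix(v, meta$V, meta$d, dimnames = list(meta$tokens, NULL))
}
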
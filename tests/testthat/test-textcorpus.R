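test_that("tokenization lowercases, strips punctuation and keeps class codes", {
  expect_identical(tokenizeReport("Fracture of left femoral neck."),
                   c("fracture", "of", "left", "femoral", "neck"))
  expect_identical(tokenizeReport("A1   A1"), c("a1", "a1"))
  expect_identical(tokenizeReport("  (mildly) displaced, fracture!  "),
                   c("mildly", "displaced", "fracture"))
  expect_error(tokenizeReport(""), "empty")
  expect_error(tokenizeReport("   \t "), "empty")
})

test_that("vocabulary keeps the most frequent tokens with lexicographic ties", {
  v <- buildVocabulary(list(c("a", "b", "b", "c", "c")), maxSize = 2)
  nonspecial <- v@tokens[-(1:4)]
  expect_setequal(nonspecial, c("b", "c"))
  expect_identical(vocabSize(v), 6L)
  # cap not binding
  v5 <- buildVocabulary(list(letters[1:5]), maxSize = 300)
  expect_identical(vocabSize(v5), 9L)
  expect_error(buildVocabulary(list()), "empty corpus")
  # PAD is id 0
  expect_identical(tokenIds(v, "<pad>"), 0L)
})

test_that("a 457-word corpus truncates to the 300 most frequent tokens", {
  set.seed(41)
  words <- sprintf("w%03d", 1:457)
  # frequency ~ rank so the kept set is unambiguous
  corpus <- lapply(1:457, function(i) rep(words[i], 458 - i))
  v <- buildVocabulary(corpus, maxSize = 300)
  nonspecial <- v@tokens[-(1:4)]
  expect_length(nonspecial, 300L)
  expect_setequal(nonspecial, words[1:300])
})

test_that("vocabulary is invariant to corpus order", {
  set.seed(5)
  corpus <- replicate(40, sample(c(letters, "a1", "b2"), sample(3:10, 1),
                                 replace = TRUE), simplify = FALSE)
  v1 <- buildVocabulary(corpus, maxSize = 10)
  v2 <- buildVocabulary(rev(corpus), maxSize = 10)
  expect_identical(v1@tokens, v2@tokens)
  expect_identical(v1@frequencies, v2@frequencies)
})

test_that("one-hot encoding pads, round-trips, and maps OOV to UNK", {
  v <- buildVocabulary(list(c("femoral", "neck", "fracture")), maxSize = 300)
  rep3 <- tokenizedReport("femoral neck fracture", v)
  oh <- encodeOneHot(rep3, v, maxLen = 40)
  expect_identical(dim(oh$matrix), c(40L, vocabSize(v)))
  expect_true(all(rowSums(oh$matrix) == 1))
  expect_identical(sum(oh$mask), 3)
  # rows beyond length are PAD one-hots
  expect_true(all(oh$matrix[4:40, 1] == 1))
  # round trip reproduces the ids
  decoded <- apply(oh$matrix[1:3, ], 1, which.max) - 1L
  expect_identical(decoded, rep3$ids)
  # OOV token hits the UNK row
  repOov <- tokenizedReport("femoral shaft", v)
  ohOov <- encodeOneHot(repOov, v, maxLen = 5)
  unkId <- tokenIds(v, "<unk>")
  expect_identical(ohOov$ids[2], unkId)
  expect_equal(which.max(ohOov$matrix[2, ]) - 1L, unkId)
  # truncation warns
  long <- tokenizedReport(paste(rep("neck", 50), collapse = " "), v, maxLen = 40)
  expect_identical(long$length, 40L)
  expect_warning(tokenizedReport(paste(rep("neck", 50), collapse = " "), v))
})

bruteCooccurrence <- function(corpus, vocab, window, weighting = "uniform") {
  V <- vocabSize(vocab)
  m <- matrix(0, V, V)
  for (toks in corpus) {
    ids <- match(toks, vocab@tokens)
    ids <- ids[!is.na(ids)]
    n <- length(ids)
    if (n < 2) next
    for (p in seq_len(n)) for (q in seq_len(n)) {
      d <- abs(p - q)
      if (p != q && d <= window)
        m[ids[p], ids[q]] <- m[ids[p], ids[q]] +
          if (weighting == "harmonic") 1 / d else 1
    }
  }
  m
}

test_that("co-occurrence counts match brute-force pair enumeration", {
  v <- buildVocabulary(list(c("a", "b")), maxSize = 10)
  cc <- buildCooccurrence(list(c("a", "b", "a")), v, window = 1)
  ia <- tokenIds(v, "a") + 1; ib <- tokenIds(v, "b") + 1
  expect_equal(cc[ia, ib], 2)
  expect_equal(cc[ib, ia], 2)
  expect_equal(cc[ia, ia], 0)
  expect_error(buildCooccurrence(list(c("a", "b")), v, window = 0), "window")

  set.seed(17)
  for (rep in 1:5) {
    corpus <- replicate(6, sample(letters[1:8], sample(2:12, 1), TRUE),
                        simplify = FALSE)
    vv <- buildVocabulary(corpus, maxSize = 6)
    for (w in c(1, 3)) {
      got <- buildCooccurrence(corpus, vv, window = w)
      want <- bruteCooccurrence(corpus, vv, w)
      expect_equal(unname(unclass(got))[seq_len(nrow(want)), ], want,
                   ignore_attr = TRUE)
      expect_equal(got, t(got), ignore_attr = TRUE)  # symmetric window
    }
  }
  # corpus that is entirely OOV yields an all-zero matrix
  zero <- buildCooccurrence(list(c("zz", "qq")), v, window = 2)
  expect_true(all(zero == 0))
})

test_that("GloVe fit is deterministic, monotone and correctly shaped", {
  set.seed(3)
  corpus <- replicate(30, sample(paste0("w", 1:20), sample(4:9, 1), TRUE),
                      simplify = FALSE)
  v <- buildVocabulary(corpus, maxSize = 20)
  cc <- buildCooccurrence(corpus, v, window = 3)
  f1 <- fitGlove(cc, d = 8, epochs = 50, seed = 9)
  f2 <- fitGlove(cc, d = 8, epochs = 50, seed = 9)
  expect_identical(f1$vectors, f2$vectors)
  expect_identical(dim(f1$vectors), c(vocabSize(v), 8L))
  expect_false(any(!is.finite(f1$vectors)))
  # objective non-increasing (full-batch with backtracking)
  expect_true(all(diff(f1$objective) <= 1e-8))
  expect_lt(f1$objective[50], f1$objective[1])
  # default dimension is 128
  f3 <- fitGlove(cc, epochs = 2, seed = 1)
  expect_identical(ncol(f3$vectors), 128L)
  expect_error(fitGlove(matrix(0, 4, 4)), "all-zero")
})

test_that("vocabulary and embeddings persist through their file formats", {
  v <- buildVocabulary(list(c("neck", "neck", "femur")), maxSize = 5)
  pv <- tempfile(fileext = ".json")
  saveVocabulary(v, pv)
  v2 <- readVocabulary(pv)
  expect_identical(v2@tokens, v@tokens)
  expect_identical(v2@frequencies, v@frequencies)

  cc <- buildCooccurrence(list(c("neck", "femur", "neck")), v, window = 1)
  emb <- fitGlove(cc, d = 6, epochs = 5, seed = 2)
  pe <- tempfile()
  saveEmbeddings(emb, pe)
  back <- readEmbeddings(pe)
  expect_equal(back, emb$vectors, ignore_attr = TRUE)
})
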
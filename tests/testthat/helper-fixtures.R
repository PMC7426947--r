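# Shared fixtures: tiny on-disk datasets and desk-scale training configs.
# Everything is generated programmatically; nothing is stored in the repo.

# A small paired dataset (64 px phantoms, mild noise so micro-training can
# make progress) written to a fresh directory.
tinyDataset <- function(counts = list(
                          train = c(normal = 6, A1 = 6, B2 = 6),
                          val = c(normal = 2, A1 = 2, B2 = 2),
                          test = c(normal = 3, A1 = 3, B2 = 3)),
                        noiseSd = 0.05, confounderProb = 0.2, seed = 101L) {
  dir <- tempfile("hipfraxtest")
  spec <- phantomSpec(imageSize = 64, noiseSd = noiseSd,
                      confounderProb = confounderProb)
  generateDataset(counts, spec, dir, seed = seed)
}

# Micro training configuration: small heads, short schedule, higher lr so a
# couple of epochs show movement.
microConfig <- function(..., epochs = 2L, seed = 7L) {
  trainConfig(epochs = epochs, batchSize = 8L, lr = 1e-3, seed = seed,
              encoder = encoderConfig(inputSize = 64, dropout = 0.2),
              classifier = classifierConfig(hidden = 16L),
              decoderHidden = 16L, embedDim = 12L, gloveEpochs = 5L,
              maxLen = 20L, ...)
}

# random probability distributions (rows sum to 1)
randomDistributions <- function(n, k) {
  m <- matrix(runif(n * k, 0.01, 1), n, k)
  m / rowSums(m)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)), tol)
}
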
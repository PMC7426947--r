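## Pipeline wiring: end-to-end comparative benchmark (generate -> augment ->
## train baseline/M1/M2 -> evaluate at 2/3/7-class levels), manifest
## validation, YAML run configuration and JSON-lines logging.

# small string hash (djb2) for embedding config fingerprints in artifacts
configHash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE,
                        null = "null")
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

logLine <- function(path, stage, ...) {
  if (is.null(path)) return(invisible())
  entry <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage = stage), list(...))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA, null = "null"),
      "\n", file = path, append = TRUE)
  invisible()
}

#' Benchmark run configuration
#'
#' Defaults define the desk-scale comparative study: 64 x 64 low-SNR
#' phantoms, the [benchmarkProfile()] class counts (~700 augmented training
#' images), the small-cnn encoder, 30 epochs, Adam at 1e-4, focal loss and
#' joint weight lambda = 0.5.
#'
#' @param outDir output directory.
#' @param seeds integer vector of master seeds; results are averaged over
#'   them.
#' @param profile class-count profile (default [benchmarkProfile()]).
#' @param imageSize phantom/encoder size (default 64).
#' @param spec a [phantomSpec()] (default: low-SNR at `imageSize`).
#' @param train a [trainConfig()] template; its seed is replaced by each
#'   run seed. The benchmark default raises the learning rate to 1e-3, the
#'   optimizer scale that suits the scaled-down schedule (30 epochs, ~1,300
#'   minibatches).
#' @param augment an [augmentationPolicy()].
#' @param levels hierarchy levels to evaluate (default `c(2, 3, 7)`).
#' @return a `RunConfig` list.
#' @export
benchmarkConfig <- function(outDir = tempfile("hipfrax"), seeds = 1L,
                            profile = benchmarkProfile(), imageSize = 64L,
                            spec = phantomSpec(imageSize = imageSize),
                            train = trainConfig(
                              lr = 1e-3,
                              encoder = encoderConfig(inputSize = imageSize)),
                            augment = augmentationPolicy(),
                            levels = c(2, 3, 7)) {
  list(outDir = outDir, seeds = as.integer(seeds), profile = profile,
       imageSize = as.integer(imageSize), spec = spec, train = train,
       augment = augment, levels = levels)
}

#' Read a benchmark configuration from YAML
#'
#' Top-level keys mirror [benchmarkConfig()] arguments; `train`, `spec` and
#' `augment` sub-maps override the corresponding constructor arguments
#' field-for-field. Unspecified fields keep their defaults.
#'
#' @param path YAML file.
#' @param ... overrides applied after the file (e.g. from CLI flags).
#' @return a `RunConfig` list.
#' @export
readRunConfig <- function(path, ...) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  over <- list(...)
  for (nm in names(over)) y[[nm]] <- over[[nm]]
  imageSize <- as.integer(y$imageSize %||% 64L)
  spec <- do.call(phantomSpec, c(list(imageSize = imageSize),
                                 y$spec %||% list()))
  trainArgs <- y$train %||% list()
  trainArgs$lr <- trainArgs$lr %||% 1e-3   # benchmark-scale default
  encArgs <- trainArgs$encoder %||% list()
  encArgs$inputSize <- imageSize
  trainArgs$encoder <- do.call(encoderConfig, encArgs)
  if (!is.null(trainArgs$classifier))
    trainArgs$classifier <- do.call(classifierConfig, trainArgs$classifier)
  train <- do.call(trainConfig, trainArgs)
  aug <- do.call(augmentationPolicy, y$augment %||% list())
  benchmarkConfig(outDir = y$outDir %||% tempfile("hipfrax"),
                  seeds = y$seeds %||% 1L,
                  profile = y$profile %||% benchmarkProfile(),
                  imageSize = imageSize, spec = spec, train = train,
                  augment = aug, levels = y$levels %||% c(2, 3, 7))
}

#' Run the three-regime comparative benchmark
#'
#' For each seed: generates one synthetic paired dataset, applies the
#' 4x-fracture augmentation to the training split, trains the image-only
#' baseline, M1 and M2 with that seed, and evaluates all three on the
#' identical test split at each hierarchy level. Returns the per-seed and
#' seed-averaged comparison table (rows = models, columns = level x
#' {accuracy, avg F1}) and writes it, the effective config, its hash and a
#' JSON-lines stage log under `config$outDir`.
#'
#' @param config a [benchmarkConfig()].
#' @param keepModels return the trained models as well (default FALSE).
#' @return list with `table` (seed-averaged), `perSeed`, `hash`, `outDir`,
#'   and optionally `models`.
#' @export
runBenchmark <- function(config = benchmarkConfig(), keepModels = FALSE) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- configHash(config[c("profile", "imageSize", "spec", "augment",
                              "levels", "seeds")])
  logPath <- file.path(config$outDir, "benchmark.log.jsonl")
  regimes <- c(base = "baseline", m1 = "m1", m2 = "m2")
  perSeed <- list()
  models <- list()
  for (seed in config$seeds) {
    dataDir <- file.path(config$outDir, sprintf("data_seed%d", seed))
    logLine(logPath, "generate", seed = seed, hash = hash)
    man <- generateDataset(config$profile, config$spec, dataDir,
                           seed = deriveSeed(seed, "data"))
    man <- augmentDataset(man, config$augment,
                          seed = deriveSeed(seed, "augment"))
    rows <- list()
    for (mk in names(regimes)) {
      tc <- config$train
      tc$regime <- regimes[[mk]]
      tc$seed <- as.integer(seed)
      logLine(logPath, "train", model = mk, seed = seed)
      model <- trainModel(man, tc)
      if (keepModels) models[[sprintf("%s_seed%d", mk, seed)]] <- model
      for (lev in config$levels) {
        ev <- evaluateModel(model, man, "test", lev)
        rows[[sprintf("%s_%s", mk, lev)]] <- data.frame(
          model = mk, level = lev, accuracy = ev$metrics$accuracy,
          avgF1 = ev$metrics$macroF1, seed = seed)
      }
      ckpt <- file.path(config$outDir,
                        sprintf("%s_seed%d.ckpt", mk, seed))
      saveCheckpoint(model, ckpt)
    }
    perSeed[[as.character(seed)]] <- do.call(rbind, rows)
    logLine(logPath, "evaluate", seed = seed)
  }
  all <- do.call(rbind, perSeed)
  rownames(all) <- NULL
  tab <- aggregate(cbind(accuracy, avgF1) ~ model + level, all, mean)
  tab <- tab[order(match(tab$model, names(regimes)), tab$level), ]
  rownames(tab) <- NULL
  write.table(cbind(tab, hash = hash),
              file.path(config$outDir, "comparison.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(hash = hash, seeds = config$seeds, table = tab, perSeed = all),
    file.path(config$outDir, "comparison.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  logLine(logPath, "done", hash = hash)
  out <- list(table = tab, perSeed = all, hash = hash,
              outDir = config$outDir)
  if (keepModels) out$models <- models
  out
}

#' Validate a dataset manifest
#'
#' Checks label validity (C-type labels are rejected: that fracture class is
#' excluded), split tags, report-pairing rules (reports only on training
#' records), id uniqueness and referenced-file existence.
#'
#' @param manifest a [DatasetManifest-class], or a path to a manifest file.
#' @param checkFiles verify that referenced image/report files exist
#'   (default TRUE when the manifest directory is known).
#' @return data.frame of violations (id, rule, message); zero rows means the
#'   manifest is well-formed.
#' @export
validateManifest <- function(manifest, checkFiles = TRUE) {
  if (is.character(manifest)) {
    # read raw (bypassing class validity) so violations can be reported
    rec <- read.delim(manifest, stringsAsFactors = FALSE)
    rec$report[rec$report %in% c("NA", "")] <- NA_character_
    dir <- dirname(manifest)
  } else {
    rec <- manifest@records
    dir <- manifest@meta$dir
  }
  bad <- list()
  flag <- function(id, rule, message)
    bad[[length(bad) + 1L]] <<- data.frame(id = id, rule = rule,
                                           message = message)
  for (i in seq_len(nrow(rec))) {
    if (!rec$label[i] %in% aoClasses())
      flag(rec$id[i], "label",
           sprintf("invalid label '%s' (C-type and unknown labels excluded)",
                   rec$label[i]))
    if (!rec$split[i] %in% c("train", "val", "test"))
      flag(rec$id[i], "split", sprintf("invalid split '%s'", rec$split[i]))
    if (!is.na(rec$report[i]) && rec$split[i] != "train")
      flag(rec$id[i], "pairing",
           sprintf("%s record carries a report", rec$split[i]))
    if (checkFiles && !is.null(dir)) {
      if (!file.exists(file.path(dir, rec$image[i])))
        flag(rec$id[i], "file", sprintf("missing image %s", rec$image[i]))
      if (!is.na(rec$report[i]) &&
          !file.exists(file.path(dir, rec$report[i])))
        flag(rec$id[i], "file", sprintf("missing report %s", rec$report[i]))
    }
  }
  dup <- rec$id[duplicated(rec$id)]
  for (d in unique(dup)) flag(d, "id", "duplicate sample id")
  if (length(bad)) do.call(rbind, bad)
  else data.frame(id = character(), rule = character(),
                  message = character())
}
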
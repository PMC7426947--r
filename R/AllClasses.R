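#' Frequency-truncated report vocabulary
#'
#' Holds the ordered token table of a report corpus: four special tokens
#' (`<pad>`, `<s>`, `</s>`, `<unk>`) followed by the most frequent corpus
#' tokens. Token ids are 0-based positions in `tokens`; `<pad>` is always
#' id 0. Out-of-vocabulary tokens map to `<unk>`.
#'
#' @slot tokens character vector, specials first, then corpus tokens in
#'   decreasing frequency (ties broken lexicographically).
#' @slot frequencies named integer vector of corpus counts for the
#'   non-special tokens.
#' @slot specials named character vector of the four special tokens.
#' @export
setClass("ReportVocabulary",
  slots = c(tokens = "character", frequencies = "integer",
            specials = "character"))

setValidity("ReportVocabulary", function(object) {
  sp <- object@specials
  msgs <- character()
  if (length(sp) != 4L || !identical(names(sp), c("pad", "start", "end", "unk")))
    msgs <- c(msgs, "specials must be named pad, start, end, unk")
  if (length(object@tokens) < length(sp) ||
      !identical(object@tokens[seq_along(sp)], unname(sp)))
    msgs <- c(msgs, "tokens must start with the special tokens (<pad> id 0)")
  nonspecial <- object@tokens[-seq_along(sp)]
  if (!all(nonspecial %in% names(object@frequencies)))
    msgs <- c(msgs, "every non-special token needs a recorded frequency")
  if (length(object@frequencies) && any(object@frequencies < 1L))
    msgs <- c(msgs, "non-special tokens must have frequency >= 1")
  if (anyDuplicated(object@tokens))
    msgs <- c(msgs, "tokens must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Dataset manifest: the single source of truth for all pipeline stages
#'
#' One row per sample: id, image path, AO/OTA label, report path (training
#' rows only; `NA` otherwise) and split tag (`train`, `val`, `test`).
#'
#' @slot records data.frame with columns `id`, `image`, `label`, `report`,
#'   `split`.
#' @slot seed integer seed the dataset was generated with (NA for external
#'   data).
#' @slot meta list of generator metadata (phantom spec, augmentation policy).
#' @export
setClass("DatasetManifest",
  slots = c(records = "data.frame", seed = "integer", meta = "list"))

setValidity("DatasetManifest", function(object) {
  rec <- object@records
  need <- c("id", "image", "label", "report", "split")
  msgs <- character()
  if (!all(need %in% names(rec)))
    return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(rec$id)) msgs <- c(msgs, "sample ids must be unique")
  if (!all(rec$split %in% c("train", "val", "test")))
    msgs <- c(msgs, "split tags must be train, val or test")
  if (!all(rec$label %in% aoClasses()))
    msgs <- c(msgs, "labels must be one of the seven AO/OTA classes")
  bad <- !is.na(rec$report) & rec$split != "train"
  if (any(bad))
    msgs <- c(msgs, "reports are only allowed on training records")
  if (length(msgs)) msgs else TRUE
})

#' Trained multimodal fracture model
#'
#' A checkpointed encoder (+ optional report decoder) + classifier triple
#' sharing one latent code. `params` holds all weight matrices; `configs`
#' the encoder/decoder/classifier/training configurations; `vocab` the
#' report vocabulary (absent for the image-only baseline).
#'
#' @slot params list of numeric weight arrays.
#' @slot configs list with elements `encoder`, `decoder`, `classifier`,
#'   `train`.
#' @slot vocab `ReportVocabulary` or `NULL`.
#' @slot regime character: `"baseline"`, `"m1"` or `"m2"`.
#' @slot seed integer training seed.
#' @slot log data.frame training log (one row per epoch per stage).
#' @export
setClass("FractureNet",
  slots = c(params = "list", configs = "list", vocab = "ANY",
            regime = "character", seed = "integer", log = "data.frame"))

setValidity("FractureNet", function(object) {
  if (!object@regime %in% c("baseline", "m1", "m2"))
    return("regime must be baseline, m1 or m2")
  if (!is.null(object@vocab) && !is(object@vocab, "ReportVocabulary"))
    return("vocab must be NULL or a ReportVocabulary")
  TRUE
})

setMethod("show", "ReportVocabulary", function(object) {
  cat(sprintf("ReportVocabulary: %d tokens (%d special + %d corpus)\n",
              length(object@tokens), length(object@specials),
              length(object@tokens) - length(object@specials)))
  nonspecial <- object@tokens[-seq_along(object@specials)]
  cat("  most frequent:", paste(head(nonspecial, 8L), collapse = " "), "\n")
})

setMethod("show", "DatasetManifest", function(object) {
  tab <- table(object@records$split)
  cat(sprintf("DatasetManifest: %d records (seed %s)\n",
              nrow(object@records), object@seed))
  for (s in names(tab)) cat(sprintf("  %-5s %d\n", s, tab[[s]]))
})

setMethod("show", "FractureNet", function(object) {
  cat(sprintf("FractureNet [%s]: latent %d-D, backbone %s, seed %d\n",
              object@regime, object@configs$encoder$latentDim,
              object@configs$encoder$backbone, object@seed))
  if (nrow(object@log))
    cat(sprintf("  trained %d logged epochs; final total loss %.4f\n",
                nrow(object@log), object@log$loss_total[nrow(object@log)]))
})

#' @describeIn ReportVocabulary-class total vocabulary size (specials
#'   included).
#' @param vocab a `ReportVocabulary`.
#' @export
vocabSize <- function(vocab) length(vocab@tokens)

#' @describeIn DatasetManifest-class the manifest record table.
#' @param manifest a `DatasetManifest`.
#' @export
manifestRecords <- function(manifest) manifest@records

#' @describeIn FractureNet-class the training log (one row per epoch/stage).
#' @param model a `FractureNet`.
#' @export
trainLog <- function(model) model@log
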
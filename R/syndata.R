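## Synthetic paired radiograph-phantom / report generator.
##
## The institutional radiographs and reports behind the original study are
## protected patient data, so this module emulates the dataset's structure:
## stylized pelvis phantoms with AO/OTA-consistent fracture motifs
## (trochanteric region for A subtypes, femoral neck for B subtypes),
## class-correlated template reports paired to training images only, severe
## class imbalance, strong non-fracture confounder edges on a fraction of
## normals, and the 4x fracture-class geometric augmentation policy.

#' Phantom rendering specification
#'
#' @param imageSize square image size in pixels (>= 64; default 128).
#' @param jitterPos anatomy translation jitter, fraction of image size.
#' @param jitterRot anatomy rotation jitter in degrees.
#' @param noiseSd additive Gaussian intensity noise SD on the \[0,1\] scale.
#'   The default (0.11) is deliberately low-SNR: fracture motifs are a few
#'   pixels wide against substantial noise, calibrated once so the
#'   image-only baseline lands in the difficulty regime of the original
#'   institutional study (7-class accuracy around two thirds).
#' @param confounderProb fraction of normal images given a strong
#'   non-fracture soft-tissue edge (the abdominal-fat-overlap confounder).
#' @return a `PhantomSpec` list.
#' @export
phantomSpec <- function(imageSize = 128L, jitterPos = 0.02, jitterRot = 5,
                        noiseSd = 0.11, confounderProb = 0.35) {
  if (imageSize < 64L) stop("imageSize must be >= 64")
  if (confounderProb < 0 || confounderProb > 1)
    stop("confounderProb must be in [0,1]")
  structure(list(imageSize = as.integer(imageSize), jitterPos = jitterPos,
                 jitterRot = jitterRot, noiseSd = noiseSd,
                 confounderProb = confounderProb),
            class = "PhantomSpec")
}

# --- vectorized raster helpers (unit coordinates, y down) ------------------

# squared distance from every grid point to segment p1-p2
segDist2 <- function(gx, gy, p1, p2) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  L2 <- vx * vx + vy * vy
  t <- if (L2 < 1e-12) rep(0, length(gx)) else
    pmin(1, pmax(0, ((gx - p1[1]) * vx + (gy - p1[2]) * vy) / L2))
  (gx - (p1[1] + t * vx))^2 + (gy - (p1[2] + t * vy))^2
}

capsuleMask <- function(gx, gy, p1, p2, w) segDist2(gx, gy, p1, p2) <= w * w
discMask <- function(gx, gy, c, r) (gx - c[1])^2 + (gy - c[2])^2 <= r * r

rot2 <- function(p, ctr, theta) {
  co <- cos(theta); si <- sin(theta)
  d <- p - ctr
  ctr + c(co * d[1] - si * d[2], si * d[1] + co * d[2])
}

#' Render a synthetic pelvic radiograph phantom
#'
#' Draws a stylized pelvis (pelvic ring, sacrum, two femoral heads, necks,
#' trochanters and shafts) with jittered pose, then overlays a dark fracture
#' motif in the label's designated anatomical region: A subtypes break the
#' trochanteric region (A1 single oblique line, A2 multifragmentary, A3
#' reverse-oblique), B subtypes the femoral neck (B1 thin subcapital line,
#' B2 transcervical gap, B3 displaced double line). Normal phantoms have no
#' fracture; a fraction of them receive a strong curved soft-tissue edge
#' (abdominal-fat confounder). Deterministic under `(label, spec, seed)`.
#'
#' @param label one of [aoClasses()].
#' @param spec a [phantomSpec()].
#' @param seed integer seed.
#' @return list with `image` (size x size matrix in \[0,1\]), binary `mask` of
#'   the fracture support (all-zero for normals), `label`, `seed`, `side`
#'   (-1 left, +1 right, 0 for normal), `regions` (trochanteric disc and
#'   neck capsule geometry of the fractured side) and `confounder` flag.
#' @export
renderPhantom <- function(label, spec = phantomSpec(), seed = 1L) {
  if (!label %in% aoClasses()) stop(sprintf("unknown label '%s'", label))
  withr::with_seed(seed, {
    N <- spec$imageSize
    px <- (seq_len(N) - 0.5) / N
    gy <- rep(px, times = N)   # row index fastest (matches matrix layout)
    gx <- rep(px, each = N)

    theta <- runif(1, -spec$jitterRot, spec$jitterRot) * pi / 180
    shift <- runif(2, -spec$jitterPos, spec$jitterPos)
    ctr <- c(0.5, 0.5)
    J <- function(p) rot2(p, ctr, theta) + shift

    img <- 0.22 + 0.08 * gy + 0.03 * sin(6 * gx)

    # pelvic ring (elliptic annulus) + sacrum
    ex <- (gx - 0.5 - shift[1]) / 0.33; ey <- (gy - 0.32 - shift[2]) / 0.20
    ring <- abs(sqrt(ex^2 + ey^2) - 1) < 0.16
    img[ring] <- img[ring] + 0.28
    sac <- abs(gx - 0.5 - shift[1]) < 0.055 & gy > 0.08 & gy < 0.45
    img[sac] <- img[sac] + 0.20

    side <- if (label == "normal") 0 else sample(c(-1, 1), 1)
    anat <- list()
    for (s in c(-1, 1)) {
      head <- J(c(0.5 + s * 0.16, 0.46))
      troch <- J(c(0.5 + s * 0.30, 0.56))
      shaftEnd <- J(c(0.5 + s * 0.33, 0.97))
      img[discMask(gx, gy, head, 0.055)] <- img[discMask(gx, gy, head, 0.055)] + 0.32
      nk <- capsuleMask(gx, gy, head, troch, 0.030)
      img[nk] <- img[nk] + 0.28
      sh <- capsuleMask(gx, gy, troch, shaftEnd, 0.045)
      img[sh] <- img[sh] + 0.30
      gt <- discMask(gx, gy, troch, 0.035)
      img[gt] <- img[gt] + 0.18
      if (s == side || (side == 0 && s == 1))
        anat <- list(head = head, troch = troch)
    }

    # fracture motif in the label's designated region; geometry is drawn
    # relative to the jittered neck axis so pose jitter moves the lesion
    # with the anatomy. Motif sizes are chosen to stay clearly visible at
    # 64 px (a few pixels wide) the way real fracture lines are at full
    # radiograph resolution.
    mask <- rep(FALSE, N * N)
    if (label != "normal") {
      head <- anat$head; troch <- anat$troch
      u <- (troch - head) / sqrt(sum((troch - head)^2))  # along neck
      v <- c(-u[2], u[1])                                 # across neck
      dark <- function(p1, p2, w) {
        m <- capsuleMask(gx, gy, p1, p2, w)
        img[m] <<- img[m] - 0.45
        mask <<- mask | m
      }
      obl <- function(ctrP, ang, len, w) {
        dirv <- cos(ang) * v + sin(ang) * u
        dark(ctrP - dirv * len / 2, ctrP + dirv * len / 2, w)
      }
      jit <- runif(1, -0.02, 0.02)       # slide along the neck axis
      trochC <- troch + jit * u
      mid <- (head + troch) / 2 + jit * u
      switch(label,
        A1 = obl(trochC, +0.6, 0.17, 0.016),
        A2 = { obl(trochC, +0.6, 0.16, 0.015)              # comminuted fan
               obl(trochC + 0.035 * u, +0.1, 0.12, 0.011)
               obl(trochC - 0.030 * u, +1.1, 0.11, 0.011) },
        A3 = obl(trochC, -0.6, 0.18, 0.017),               # reverse oblique
        B1 = obl(head + 0.30 * (troch - head) + jit * u,
                 0.15, 0.10, 0.010),                        # subcapital
        B2 = obl(mid, 0.0, 0.13, 0.019),                    # transcervical
        B3 = { obl(mid, 0.0, 0.13, 0.026)                   # displaced
               obl(mid + 0.035 * u, 0.45, 0.11, 0.013) })
    }

    confounder <- FALSE
    if (label == "normal" && runif(1) < spec$confounderProb) {
      confounder <- TRUE
      # fracture-like soft-tissue edge (abdominal-fat / skin-fold overlap):
      # a dark streak crossing the proximal femur region but off the bone
      # axis, the shortcut that traps purely image-driven classifiers
      s <- sample(c(-1, 1), 1)
      base <- J(c(0.5 + s * 0.26, 0.52)) + runif(2, -0.04, 0.04)
      ang <- runif(1, -0.5, 0.5)
      dirv <- c(cos(ang) * 0.5 - s * sin(ang), sin(ang) * 0.5 + s * cos(ang))
      dirv <- dirv / sqrt(sum(dirv^2))
      p1 <- base - dirv * 0.11; p2 <- base + dirv * 0.11
      e1 <- capsuleMask(gx, gy, p1, p2, 0.014)
      img[e1] <- img[e1] - 0.35
      off <- c(-dirv[2], dirv[1]) * 0.035
      e2 <- capsuleMask(gx, gy, p1 + off, p2 + off, 0.009)
      img[e2] <- img[e2] - 0.18
    }

    img <- img + rnorm(N * N, 0, spec$noiseSd)
    img <- pmin(1, pmax(0, img))

    list(image = matrix(img, N, N), mask = matrix(mask + 0, N, N),
         label = label, seed = as.integer(seed), side = side,
         regions = list(
           trochanteric = list(center = anat$troch %||% J(c(0.80, 0.56)),
                               radius = 0.10),
           neck = list(p1 = anat$head %||% J(c(0.66, 0.46)),
                       p2 = anat$troch %||% J(c(0.80, 0.56)), w = 0.055)),
         confounder = confounder)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Class-keyword report templates
#'
#' Template reports per AO/OTA class with slot markers (`{side}`,
#' `{displacement}`, ...) filled from small synonym pools. Every fracture
#' class carries a distinctive anatomical keyword (A1 pertrochanteric/simple,
#' A2 comminuted, A3 reverse oblique, B1 subcapital, B2 transcervical,
#' B3 basicervical), mirroring how clinical reports state fracture location
#' and type. The total lexicon stays far below the 457-word corpus cap.
#'
#' @return list with `templates` (per-class pattern vectors) and `pools`
#'   (synonym pools for the slot markers).
#' @export
reportTemplates <- function() {
  list(
    templates = list(
      normal = c(
        "no acute fracture or dislocation of the {side} hip",
        "both hips are unremarkable with intact cortical margins",
        "no evidence of acute bony injury {quality}",
        "normal appearance of both proximal femurs without fracture"),
      A1 = c(
        "simple pertrochanteric fracture of the {side} femur {displacement}",
        "two part pertrochanteric fracture at the {side} trochanteric region {displacement}",
        "simple intertrochanteric fracture line of the {side} hip {displacement}"),
      A2 = c(
        "comminuted pertrochanteric fracture of the {side} femur {displacement}",
        "multifragmentary comminuted intertrochanteric fracture on the {side} {displacement}",
        "comminuted fracture of the {side} trochanteric region with multiple fragments"),
      A3 = c(
        "reverse oblique intertrochanteric fracture of the {side} femur {displacement}",
        "reverse oblique fracture line across the {side} trochanteric region {displacement}",
        "intertrochanteric fracture of reverse oblique pattern on the {side}"),
      B1 = c(
        "impacted subcapital fracture of the {side} femoral neck {displacement}",
        "subcapital fracture of the {side} femur with valgus impaction",
        "incomplete subcapital fracture line at the {side} femoral neck"),
      B2 = c(
        "transcervical fracture of the {side} femoral neck {displacement}",
        "complete transcervical fracture through the {side} femoral neck {displacement}",
        "transcervical fracture line of the {side} hip {displacement}"),
      B3 = c(
        "displaced basicervical fracture of the {side} femoral neck",
        "basicervical fracture of the {side} femur with marked displacement",
        "severely displaced basicervical fracture at the {side} femoral neck")),
    pools = list(
      side = c("left", "right"),
      displacement = c("without displacement", "with mild displacement",
                       "with displacement", "minimally displaced"),
      quality = c("on this examination", "of either hip",
                  "on the current study")))
}

#' Generate a class-consistent synthetic radiology report
#'
#' @param label one of [aoClasses()].
#' @param templates template set from [reportTemplates()].
#' @param seed integer seed.
#' @return a single report string.
#' @export
generateReport <- function(label, templates = reportTemplates(), seed = 1L) {
  tpl <- templates$templates[[label]]
  if (is.null(tpl)) stop(sprintf("no report template for label '%s'", label))
  withr::with_seed(seed, {
    txt <- sample(tpl, 1)
    for (slot in names(templates$pools)) {
      pat <- paste0("{", slot, "}")
      while (grepl(pat, txt, fixed = TRUE)) {
        repl <- sample(templates$pools[[slot]], 1)
        txt <- sub(pat, repl, txt, fixed = TRUE)
      }
    }
    txt
  })
}

#' Classify a report by its class keywords
#'
#' Rule-based inverse of [generateReport()]: looks for the distinctive
#' per-class keywords. Used as a sanity bound on how informative generated
#' reports are about the class.
#'
#' @param text report string.
#' @return predicted class label.
#' @export
keywordClassifyReport <- function(text) {
  t <- tolower(text)
  if (grepl("reverse", t)) "A3"
  else if (grepl("comminuted|multifragmentary", t)) "A2"
  else if (grepl("pertrochanteric|intertrochanteric", t)) "A1"
  else if (grepl("subcapital", t)) "B1"
  else if (grepl("transcervical", t)) "B2"
  else if (grepl("basicervical", t)) "B3"
  else "normal"
}

# ---------------------------------------------------------------------------

#' Read and write grayscale images
#'
#' Thin PNG wrappers; images are plain numeric matrices in \[0,1\] (8/16-bit
#' PNGs are accepted on read, multi-channel PNGs are averaged to gray).
#'
#' @param image numeric matrix in \[0,1\].
#' @param path file path.
#' @export
writeImage <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)  # matrix first: keeps dims
  invisible(path)
}

#' @rdname writeImage
#' @export
readImage <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- apply(x[, , seq_len(min(3, dim(x)[3])),
                                         drop = FALSE], c(1, 2), mean)
  x
}

#' Class-count profile of the original institutional study
#'
#' Split totals of the original institutional study: 239 fracture + 220
#' normal paired training cases, 59/41 validation, 112/115 test; the training
#' B3 class has only 5 cases. The per-class allocation of the remaining
#' fracture counts is a synthetic choice constrained to those totals.
#'
#' @return list of named per-class counts for `train`, `val`, `test`.
#' @export
studyProfile <- function() {
  list(
    train = c(normal = 220, A1 = 60, A2 = 70, A3 = 20, B1 = 40, B2 = 44, B3 = 5),
    val   = c(normal = 41,  A1 = 16, A2 = 18, A3 = 6,  B1 = 10, B2 = 7,  B3 = 2),
    test  = c(normal = 115, A1 = 30, A2 = 35, A3 = 10, B1 = 20, B2 = 15, B3 = 2))
}

#' Desk-scale benchmark profile
#'
#' Scaled-down study condition for the comparative benchmark: about 700
#' training images after 4x fracture augmentation (150 fracture x 4 + 100
#' normal), 100 validation and 200 test images, keeping the severe imbalance
#' (B3 = 5 training cases).
#'
#' @return list of named per-class counts for `train`, `val`, `test`.
#' @export
benchmarkProfile <- function() {
  list(
    train = c(normal = 100, A1 = 40, A2 = 35, A3 = 25, B1 = 25, B2 = 20, B3 = 5),
    val   = c(normal = 40,  A1 = 14, A2 = 12, A3 = 10, B1 = 10, B2 = 10, B3 = 4),
    test  = c(normal = 100, A1 = 25, A2 = 22, A3 = 16, B1 = 18, B2 = 14, B3 = 5))
}

#' Generate a synthetic paired dataset on disk
#'
#' Renders phantoms and reports per the class-count profile, writes images
#' (PNG), fracture masks, reports (training split only; validation and test
#' images are unpaired) and a tab-delimited manifest with a JSON metadata
#' sidecar. Deterministic under `seed`.
#'
#' @param classCounts list of named per-class counts for `train`, `val`,
#'   `test` (e.g. [studyProfile()] or [benchmarkProfile()]).
#' @param spec a [phantomSpec()].
#' @param dir output directory (created if needed).
#' @param seed master seed; per-sample seeds are derived from it.
#' @param writeMasks write ground-truth fracture masks next to the images
#'   (default TRUE; needed for saliency scoring).
#' @return a [DatasetManifest-class].
#' @export
generateDataset <- function(classCounts, spec = phantomSpec(), dir, seed = 1L,
                            writeMasks = TRUE) {
  stopifnot(all(c("train", "val", "test") %in% names(classCounts)))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "reports"), showWarnings = FALSE)
  if (writeMasks) dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  templates <- reportTemplates()
  rows <- list()
  for (split in c("train", "val", "test")) {
    counts <- classCounts[[split]]
    for (lab in names(counts)) {
      n <- counts[[lab]]
      if (n < 0) stop("class counts must be >= 0")
      for (i in seq_len(n)) {
        id <- sprintf("%s_%s_%03d", split, lab, i)
        sseed <- deriveSeed(seed, id)
        ph <- renderPhantom(lab, spec, sseed)
        imgPath <- file.path("images", paste0(id, ".png"))
        writeImage(ph$image, file.path(dir, imgPath))
        if (writeMasks && lab != "normal")
          writeImage(ph$mask, file.path(dir, "masks", paste0(id, ".png")))
        repPath <- NA_character_
        if (split == "train") {
          repPath <- file.path("reports", paste0(id, ".txt"))
          writeLines(generateReport(lab, templates, deriveSeed(seed, paste0(id, ":rep"))),
                     file.path(dir, repPath))
        }
        rows[[id]] <- data.frame(id = id, image = imgPath, label = lab,
                                 report = repPath, split = split,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  man <- new("DatasetManifest", records = records, seed = as.integer(seed),
             meta = list(dir = dir, spec = unclass(spec)))
  writeManifest(man, file.path(dir, "manifest.tsv"))
  man
}

#' Write / read a dataset manifest
#'
#' Tab-delimited record table with header plus a JSON metadata sidecar
#' (`<path>.json`) holding the seed and generator settings.
#'
#' @param manifest a [DatasetManifest-class].
#' @param path manifest file path.
#' @export
writeManifest <- function(manifest, path) {
  write.table(manifest@records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(seed = manifest@seed, meta = manifest@meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  rec <- read.delim(path, stringsAsFactors = FALSE)
  rec$report <- as.character(rec$report)
  rec$report[rec$report %in% c("NA", "")] <- NA_character_
  meta <- list(); seed <- NA_integer_
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    m <- jsonlite::read_json(side, simplifyVector = TRUE)
    meta <- m$meta; seed <- as.integer(m$seed)
  }
  if (is.null(meta$dir)) meta$dir <- dirname(path)
  new("DatasetManifest", records = rec, seed = seed, meta = meta)
}

#' Geometric augmentation policy
#'
#' The parameter grids of the training-set augmentation: rotation -10..10
#' degrees (1-degree steps), scale 90..110 percent (1-percent steps),
#' translation -10..10 pixels per axis (1-pixel steps). Each non-exempt
#' training image is kept and `expansionFactor - 1` transformed copies are
#' added; the normal class is exempt by default and validation/test splits
#' are never touched.
#'
#' @param rotation,scale,translation integer parameter grids.
#' @param expansionFactor final per-class multiple of the original count.
#' @param exemptClasses labels excluded from expansion.
#' @return an `AugmentationPolicy` list.
#' @export
augmentationPolicy <- function(rotation = -10:10, scale = 90:110,
                               translation = -10:10, expansionFactor = 4L,
                               exemptClasses = "normal") {
  if (!length(rotation) || !length(scale) || !length(translation))
    stop("augmentation parameter grids must be non-empty")
  structure(list(rotation = as.integer(rotation), scale = as.integer(scale),
                 translation = as.integer(translation),
                 expansionFactor = as.integer(expansionFactor),
                 exemptClasses = exemptClasses),
            class = "AugmentationPolicy")
}

#' Apply a rotation/scale/translation to an image
#'
#' Rotates about the image center, scales about the center, then translates;
#' bilinear interpolation with zero fill outside the source. Parameters must
#' lie on the augmentation grids (integer degrees/percent/pixels in the
#' stated ranges).
#'
#' @param image numeric matrix.
#' @param rotationDeg integer degrees in -10..10.
#' @param scalePct integer percent in 90..110.
#' @param tx,ty integer pixel shifts in -10..10 (tx = columns, ty = rows).
#' @return transformed matrix of the same shape.
#' @export
applyTransform <- function(image, rotationDeg, scalePct, tx, ty) {
  ongrid <- function(v, grid) length(v) == 1L && !is.na(v) &&
    v == round(v) && v %in% grid
  if (!ongrid(rotationDeg, -10:10) || !ongrid(scalePct, 90:110) ||
      !ongrid(tx, -10:10) || !ongrid(ty, -10:10))
    stop("transform parameters must lie on the augmentation grids")
  H <- nrow(image); W <- ncol(image)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  th <- rotationDeg * pi / 180
  s <- scalePct / 100
  r <- rep(seq_len(H), times = W); c0 <- rep(seq_len(W), each = H)
  # invert: forward is p' = s * R(p - ctr) + ctr + t
  dy <- (r - cy - ty) / s; dx <- (c0 - cx - tx) / s
  sy <- cos(-th) * dy - sin(-th) * dx + cy
  sx <- sin(-th) * dy + cos(-th) * dx + cx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  val <- function(yy, xx) {
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    v <- numeric(length(yy))
    v[ok] <- image[cbind(yy[ok], xx[ok])]
    v
  }
  out <- (1 - fy) * (1 - fx) * val(y0, x0) +
         fy * (1 - fx) * val(y0 + 1, x0) +
         (1 - fy) * fx * val(y0, x0 + 1) +
         fy * fx * val(y0 + 1, x0 + 1)
  matrix(out, H, W)
}

#' Expand the training split by grid-sampled geometric transforms
#'
#' Keeps every training image and adds `expansionFactor - 1` transformed
#' copies for each image of a non-exempt class, with rotation/scale/
#' translation parameters drawn uniformly from the policy grids. Exempt
#' classes (default: normal) and the validation/test splits are unchanged.
#' Augmented records keep their source record's report pairing.
#'
#' @param manifest a [DatasetManifest-class] (its images must exist under
#'   `manifest@meta$dir`).
#' @param policy an [augmentationPolicy()].
#' @param seed integer seed for parameter sampling.
#' @return a new [DatasetManifest-class] including the augmented records.
#' @export
augmentDataset <- function(manifest, policy = augmentationPolicy(), seed = 1L) {
  rec <- manifest@records
  if (!any(rec$split == "train")) stop("manifest has no training split")
  dir <- manifest@meta$dir
  expand <- rec$split == "train" & !(rec$label %in% policy$exemptClasses)
  newRows <- list()
  withr::with_seed(seed, {
    for (i in which(expand)) {
      img <- NULL
      for (k in seq_len(policy$expansionFactor - 1L)) {
        par <- c(sample(policy$rotation, 1), sample(policy$scale, 1),
                 sample(policy$translation, 1), sample(policy$translation, 1))
        if (is.null(img)) img <- readImage(file.path(dir, rec$image[i]))
        aug <- applyTransform(img, par[1], par[2], par[3], par[4])
        id <- sprintf("%s_aug%d", rec$id[i], k)
        path <- file.path("images", paste0(id, ".png"))
        writeImage(aug, file.path(dir, path))
        newRows[[id]] <- data.frame(id = id, image = path,
                                    label = rec$label[i],
                                    report = rec$report[i], split = "train",
                                    stringsAsFactors = FALSE)
      }
    }
  })
  out <- rbind(rec, do.call(rbind, newRows))
  rownames(out) <- NULL
  meta <- manifest@meta
  meta$policy <- unclass(policy)
  meta$augmentSeed <- as.integer(seed)
  new("DatasetManifest", records = out, seed = manifest@seed, meta = meta)
}
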
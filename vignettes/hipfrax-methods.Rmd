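---
title: "Auxiliary-text training for fracture classification: models and methods"
author: "hipfrax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auxiliary-text training for fracture classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Radiology reports and radiographs carry complementary information, but at
diagnosis time only the image is available. hipfrax implements a multimodal
training scheme for AO/OTA proximal-femur fracture classification (seven
classes: normal, trochanteric A1–A3, femoral-neck B1–B3; the rare C types
are excluded) in which the paired report supervises training but is never
consulted at inference.

An image encoder compresses the radiograph into a 64-dimensional latent
code \(z\). Two heads consume \(z\):

* a **report decoder** — a bidirectional LSTM that, teacher-forced with the
  one-hot token sequence of the paired report, must restore that report;
  \(z\) is linearly projected to the initial hidden (and, by default, cell)
  states of both directions;
* a **classifier** — exactly two fully-connected layers producing 7-class
  logits, softmaxed at prediction time.

Three training regimes are compared:

* **baseline** — encoder + classifier only, reports ignored;
* **M1** — two stages: encoder + decoder minimize the reconstruction
  cross-entropy alone; then the classifier is trained on the (frozen)
  encoder's latent codes;
* **M2** — single stage minimizing the joint loss
  \(L = L_{cls} + \lambda\, L_{enc\text{-}dec}\) with \(\lambda = 0.5\),
  both heads updating the shared latent.

The hypothesis the package's benchmark probes is that report restoration
pressures the latent space to carry the class-relevant content that reports
make explicit, so the image-only classifier generalizes better than the
same encoder trained on images alone.

## Losses

Reconstruction uses per-step cross-entropy between the decoder's softmax
output and the one-hot target token, summed over the real (non-PAD) steps
of a report and averaged over the batch; PAD steps contribute exactly zero.
Classification uses either plain cross-entropy or, by default, the **focal
loss** \(-\alpha_t (1-p_t)^\gamma \log p_t\) with \(\gamma = 2\) and
\(\alpha\) the inverse class frequency normalized to mean one — the class
distribution is severely imbalanced (down to 5 training cases in class B3),
and focal weighting keeps the majority classes from dominating the
gradient. Probabilities are clamped at \(10^{-12}\) inside logarithms.

All four losses are exported as testable scalar functions
(`encoderDecoderLoss()`, `classifierLoss()`, `focalLoss()`, `jointLoss()`)
and are verified against independent scalar-arithmetic oracles in the test
suite; the focal loss reduces exactly to cross-entropy at \(\gamma = 0\).

## Text pipeline

Reports are lowercased, split on whitespace, and stripped of leading and
trailing punctuation (class codes such as "a1" survive intact). The
vocabulary keeps the 300 most frequent corpus tokens — frequency ties
broken lexicographically so the vocabulary is invariant to corpus order —
behind four specials (`<pad>` is always id 0, plus start/end/unknown).
Reports are capped at 40 tokens, the corpus maximum; the one-hot encoding
of a report is a 40 × V binary matrix with a mask marking real tokens.

Word embeddings (128-D) are fitted on the global word–word co-occurrence
matrix by the weighted least-squares objective
\(\sum_{X_{ij}>0} f(X_{ij})(w_i^\top\tilde w_j + b_i + \tilde b_j -
\log X_{ij})^2\), \(f(x) = \min((x/x_{max})^{0.75}, 1)\), minimized by
full-batch gradient descent with backtracking (the step halves whenever the
objective would rise), which makes the objective provably non-increasing —
a property the test suite asserts — and the fit deterministic under a seed.
The embedding layer is initialized from these vectors and fine-tuned by
default; frozen and from-scratch variants are configuration options, since
the original description supports several readings.

## Networks and optimization

The default **small-cnn** encoder is four conv(3×3)/ReLU/max-pool blocks
with 6/12/24/48 channels, global average pooling and one fully-connected
layer to the 64-D latent; an **inception-like** backbone (parallel
1×1/3×3/5×5 branches) is provided behind the same interface for fidelity
runs. Channel widths are sized so the full three-regime benchmark runs at
desk scale; the latent contract, not the layer inventory, is what the
regimes share. All forward and backward passes are written against a small
compiled core (im2col convolution, pooling, batched LSTM BPTT) and verified
against central finite differences to ~1e-7 relative error in the tests.

Optimization is Adam. `trainConfig()` defaults to the full-scale setting
(learning rate 1e-4, batch 16, 30 epochs per stage, dropout 0.5). Two
regularization placements differ deliberately from the blanket
"every layer" prescription:

* encoder dropout (rate 0.5) applies to the deepest (final-pool) feature
  maps only — stacking four 0.5-dropouts starves a net this small of
  signal; in calibration runs every regime collapsed to a constant
  predictor;
* decoder input dropout is **token-granular**: entire word embeddings are
  blanked with probability 0.5, making teacher-forced restoration
  cloze-like. With elementwise dropout the bidirectional decoder can copy
  its own input and the latent code receives almost no supervision from the
  text.

Input intensities are centered (\(x - 0.5\)) inside the encoder: with raw
\([0,1]\) images the first layer is poorly conditioned and short schedules
can stall at a constant predictor. In the joint objective the
reconstruction term is reduced **per token** (mean over each report's real
steps, then over the batch) so its gradient scale does not depend on
report length and \(\lambda = 0.5\) weighs the two objectives at
comparable per-term scale — the convention of mainstream framework loss
reductions; the exported `encoderDecoderLoss()` keeps the summed-over-steps
definition for reporting and testing.

Teacher forcing feeds the full target sequence to the decoder (a
bidirectional decoder cannot generate autoregressively; the objective is
restoration, not free generation). Training batches unroll to the batch's
longest report rather than all 40 steps; PAD tails carry no information and
are masked from the loss either way, and each sample's reverse-direction
pass runs over the sequence reversed *within its true length*, so padding
never feeds the states at real positions.

Training always runs the full schedule, but the parameters returned are
those of the epoch with the best validation accuracy (`selectBest`,
default on; no gradient ever flows from validation or test data). The
validation split exists for model selection, and on short schedules the
final epoch is a high-variance draw; selecting the supported operating
point is what the split is for. Early stopping — truncating the schedule —
remains off by default.

A single master seed fans out via a documented hash to weight
initialization, data shuffling, dropout masks, augmentation sampling and
the embedding pre-fit; training logs are bit-reproducible at a fixed BLAS
thread count.

## Synthetic data: what it emulates, and what it does not

The institutional radiographs and reports behind the original study are
protected patient data, so `generateDataset()` fabricates the dataset's
*structure*:

* stylized pelvis phantoms — pelvic ring, sacrum, femoral heads, necks,
  trochanters, shafts — with pose jitter, under additive Gaussian noise;
* fracture motifs drawn in the label's designated anatomical region
  (A subtypes in the trochanteric region: single oblique line, comminuted
  fan, reverse-oblique; B subtypes in the neck: thin subcapital line,
  transcervical gap, displaced double line), with a per-sample binary
  lesion mask kept as ground truth for saliency scoring;
* template reports with class-specific anatomical keywords
  (pertrochanteric, comminuted, reverse oblique, subcapital, transcervical,
  basicervical) and synonym jitter, within a lexicon far below the 457-word
  corpus cap; a keyword classifier recovers the class from clean templates
  with ≥99% accuracy, the documented lower bound on generator
  informativeness;
* pairing rules of the study: reports exist for training records only;
  validation and test images are unpaired;
* **confounders**: a fraction (default 0.35) of normal images receives a
  dark, fracture-like soft-tissue edge crossing the proximal femur region
  but off the bone axis — the abdominal-fat-overlap shortcut that trapped
  the image-only models in the original error analysis;
* the published augmentation policy: rotation −10…10° (1° grid), scale
  90–110% (1% grid), translation ±10 px (1 px grid), bilinear
  interpolation, zero fill, composed rotate→scale→translate about the
  image center; each non-exempt training image is kept plus three
  transformed copies (4× expansion), normals exempt, validation/test
  untouched.

Two class-count profiles ship with the package. `studyProfile()` carries
the institutional split totals (239 fracture + 220 normal paired training
cases, 59/41 validation, 112/115 test; B3 = 5 training cases), which
reproduce the study's bookkeeping exactly: 239 × 4 + 220 = 1,176 training
samples after augmentation and a 227-image test set. The per-class
allocation of the remaining fracture counts is a synthetic choice
constrained to those totals. `benchmarkProfile()` is the desk-scale
condition used by the comparative benchmark: ~700 training images after
augmentation, 100 validation, 200 test, imbalance preserved.

Default rendering parameters were calibrated once and not revisited:
`noiseSd = 0.11` places the image-only baseline's 7-class accuracy near
the band the original study reports for its image-only network (about two
thirds), and motif sizes are a few pixels at 64 px — visible the way real
fracture lines are at full radiograph resolution, hard the way they are at
thumbnail scale.

What the phantoms do **not** emulate: real anatomy and projection physics,
exposure/dynamic-range variation, device/institution shift, free-text
report diversity beyond templates, or label noise. A passing benchmark
therefore shows that the training framework extracts and transfers
class-relevant structure between the modalities under controlled
conditions — not that it reaches clinical performance on real radiographs.

## Evaluation

`confusionMatrix()` counts actual × predicted over the fixed class order;
per-class one-vs-rest TP/FP/FN/TN feed the printed formulas (accuracy,
precision, recall, F1). The average F1 is the unweighted macro mean — with
a 5-sample class, frequency weighting would hide exactly the classes the
method is about. Ratios with zero denominators are reported as 0 and
flagged rather than NaN (the rare class is routinely never predicted).
The 7-class matrix collapses down the label hierarchy (7 → 3: normal/A/B;
3 → 2: normal/fracture); collapsing conserves totals and commutes, both
asserted property-style in the tests. One-vs-rest ROC AUC uses the
rank-sum formulation (ties count one half), verified against brute-force
pairwise comparison. Latent codes are exported as a plain table for
external 2-D embedding; the embedding itself is out of scope.

## Saliency

Grad-CAM: the gradient of the **pre-softmax** class score with respect to a
convolutional layer's feature maps is global-average-pooled into neuron
importance weights \(\alpha_k\); the ReLU-rectified weighted feature-map
sum is the coarse saliency map, bilinearly upsampled and max-normalized for
overlays (an all-zero map stays all-zero without division). The default
target is the encoder's last convolutional layer. Because the synthetic
samples carry lesion masks, `saliencyMaskOverlap()` turns the qualitative
"does the model look at the fracture site?" question into a statistic: the
fraction of saliency mass inside the mask versus the mask's area fraction
(what a uniform map would score).

## The comparative benchmark

`runBenchmark()` generates one synthetic dataset per seed, trains all three
regimes with that seed, and evaluates them on the identical test split at
the 2/3/7-class levels, averaging over seeds (default configuration:
64 × 64 phantoms, `benchmarkProfile()` counts, small-cnn encoder, 30
epochs, batch 16, focal loss, \(\lambda = 0.5\), Adam at 1e-3 — the
optimizer scale suited to the short scaled-down schedule; the 1e-4 default
of `trainConfig()` is the full-scale setting). Problem sizes were chosen so
the whole bundle runs on a single desktop CPU core in minutes. The
acceptance script replays this benchmark from scratch and writes the
resulting accuracies alongside the bookkeeping and oracle-agreement
quantities.

## Numerical choices and degenerate inputs

* log-probability clamp 1e-12; softmax computed with row-max subtraction;
* vocabulary ties broken lexicographically; empty corpora and all-zero
  co-occurrence matrices are errors, not silent zeros;
* reports longer than 40 tokens truncate with a warning (the corpus
  maximum makes this unreachable for generated data);
* transform parameters must lie exactly on the augmentation grids;
  off-grid values are errors;
* zero-denominator metrics report 0 with an `undefined` flag;
* single-class AUC is NA with a warning;
* all-zero saliency maps normalize to all-zero overlays.

## Known limitations

* The phantom generator is structural, not anatomical; absolute accuracies
  are not comparable to the published institutional results.
* The auxiliary-text benefit is regime-dependent. The original study
  operates where a large encoder overfits 459 paired images and report
  reconstruction acts as a regularizer. At desk scale the small, augmented
  baseline does not overfit, and the benchmark accordingly shows the text
  benefit at the coarse (2- and 3-class) levels while the 7-class
  comparison lands within seed noise of a tie. Single-run accuracies at
  200 test images carry a standard error of several points; conclusions
  should rest on the seed-averaged table, not one run.
* M1's two-stage protocol transfers less class signal at desk scale than
  in the original study: the focal-weighted two-layer head does not reach
  the operating point its reconstruction-trained latents support within
  the short schedule. Its value here is protocol fidelity (stage
  separation, encoder freezing), which the tests pin down.
* Training is single-threaded-deterministic by contract; results are
  reproducible at a fixed BLAS thread count but may differ across BLAS
  builds in the last few bits.
* The CLI (`inst/cli/hipfrax.R`) is a thin wrapper over the exported
  functions; it adds no behavior of its own.
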
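---
title: "Perceptive-feature CAD for breast masses: models, phantom and evaluation"
author: "perceptcad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perceptive-feature CAD for breast masses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Radiologists describe breast masses on mammography with the BI-RADS
lexicon — shape, margin sharpness, microlobulated and spiculated margins,
density — and these descriptions carry most of the diagnostic signal that
separates benign from malignant masses. `perceptcad` implements a
computer-aided diagnosis pipeline built around that observation: instead of
training a network end-to-end on biopsy labels, a convolutional network is
first trained to *regress the quantified BI-RADS description* of a mass,
and the activations of its 128-unit penultimate layer ("perceptive
features") are then fed to a classical statistical classifier. The package
also implements the arithmetic of a two-session (unaided vs. CAD-aided)
multi-reader multi-case (MRMC) observer study, and a synthetic lesion
phantom so that the whole pipeline is exercisable and testable without
patient data.

## Descriptor quantification

Mass descriptions are mapped to a five-dimensional code vector in the fixed
ordering [shape, margin sharpness, microlobulated, spiculated, density].
Findings associated with malignancy are coded 1, uncertain findings 0.5,
benign findings 0:

| field | terms | codes |
|---|---|---|
| shape | oval/round, irregular | 0, 1 |
| margin sharpness | circumscribed, obscured, indistinct | 0, 0.5, 1 |
| microlobulated margins | no, yes | 0, 1 |
| spiculated margins | no, yes | 0, 1 |
| density | low/fat-containing, equal, high | 0, 0.5, 1 |

So "an irregular mass with obscured and microlobulated margins and high
density" quantifies to `[1, 0.5, 1, 0, 1]`. The vocabulary ships as a
versioned JSON resource; `parse_report_line()` is deliberate keyword
spotting over this closed vocabulary, not free-text NLP — structured report
phrases are the only supported input, and density is treated as a mandatory
field (reports without a density phrase are rejected rather than guessed).

```{r}
library(perceptcad)
quantify(parse_report_line(
  "An irregular mass with obscured and microlobulated margins and high density"))
#> <descriptor_vector> [ 1, 0.5, 1, 0, 1 ]
```

## Stage 1 — the feature extractor

The extractor is a two-channel VGG16-style network: channel 1 is the image
patch min–max normalized to [0, 1], channel 2 the binary ROI mask. Thirteen
3×3 convolution layers in five blocks (2-2-3-3-3) with ReLU and 2×2
max-pooling are followed by three fully connected layers, the last of which
has 128 units; a linear 5-unit head regresses the descriptor codes under a
mean-squared-error loss with Adam. The learning rate is piecewise constant:
at full scale it starts at 1e-4 and decays by a factor 0.1 at epochs 30 and
60, with the weights frozen at the final epoch (70 by default; freezing at
a fixed epoch rather than by early stopping is the default because the
validation loss plateaus well before it). After freezing, the output head
is discarded and `extract_features()` returns the 128 post-ReLU penultimate
activations — a pure function of (weights, patch).

Choices the architecture description leaves open, and what this package
does:

* **Initialization.** Literal standard-normal initialization destabilizes a
  13-layer network, so the default is variance-scaled Gaussian
  (He) initialization; `init_scheme = "paper_normal"` retains the
  standard-normal option.
* **Dropout and batch size** are unstated upstream of this implementation;
  defaults are 0.5 (after the first two fully connected layers, as in
  VGG16) and 16.
* **Input normalization** is per-patch min–max; intensity statistics are
  not standardized across patches.
* **Head.** The 5-unit output is linear (no squashing): the targets
  {0, 0.5, 1} are regressed directly.

The network core is implemented in C++ (RcppArmadillo, single precision,
im2col + GEMM) with every source of randomness — initialization, epoch
shuffling, dropout — drawn from R's RNG, so `set.seed()` makes training
bit-reproducible on a given platform.

**Desk-scale profile.** `extractor_test_profile()` preserves the feature
contract (128-unit penultimate layer) while downsizing everything else so
the network trains in minutes on one CPU: 64-px input, convolution widths at
1/8 of VGG16, fully connected sizes (256, 128, 128), Adam at 1e-3 decayed by
0.1 at epoch 18, 24 epochs. The higher learning rate compensates for the
roughly four-fold shorter schedule; 24 epochs was set after observing that
the held-out descriptor regression error of the downsized network is still
falling at 16.

## Stage 2 — selection, LDA, fusion

Classification is lesion-wise: each view of each case is one sample, both
views of a case sharing the case's descriptor codes (Stage 1) and pathology
label (Stage 2). `stepwise_select()` is classical forward–backward stepwise
regression of the 0/1 label on the 128 features: a feature enters when its
partial-F p-value is below `p_enter` = 0.05 and leaves when its removal
p-value exceeds `p_remove` = 0.10 — the defaults of the classical
`stepwisefit` procedure, the only defaults in evidence. Ties break by lowest
p-value, then lowest column index, making selection deterministic; constant
columns can never enter. `fit_lda()` is the equal-covariance Gaussian
discriminant with class means, pooled covariance, and empirical class
priors (uniform optional); a singular pooled covariance is regularized by
adding `1e-6 * trace/d` to the diagonal. Its posterior for the malignant
class is the probability of malignancy (POM).

Cross-validation (`crossval_train()`, K = 10 by default) divides the
training cases at *case level* — both views of a case always share a fold,
so a lesion can never inform the model that validates it — stratified by
pathology label by default (an unstratified mode exists; stratification is
an interpretation, as is case-level assignment, both chosen to prevent
leakage). Per fold, Stage 1 then Stage 2 are trained on the other K−1
folds, yielding K member models. At test time each member scores both views,
the view POMs are averaged per case, and the member case scores are averaged
into the fused POM (`fused_pom()`). Posteriors, not discriminant scores, are
averaged — the fused quantity is an "averaged probability of malignancy" —
and the fused POM is therefore always inside the member POM range.

## The phantom

`generate_dataset()` emulates the data this pipeline was designed for: per
case, two views (CC, MLO) that are independent renders sharing one
descriptor vector, a 2-D patch plus binary ROI mask per view, and a
pathology label drawn from a logistic model of the codes.

The lesion boundary is a star-shaped radial function around the patch
centre. Shape code 0 gives a mild ellipse (axis ratio up to 1.15); code 1
multiplies the radius by a random low-order harmonic jag. Microlobulation
adds a sinusoidal undulation of amplitude 0.12·r0 (8–12 lobes) — kept at
or above one pixel at the 64-px desk scale, because a sub-pixel undulation
would make the code invisible in the rendered image; spiculation adds 6–12
narrow radial Gaussian spikes (amplitude 0.3–0.5·r0, saturating where
spikes overlap). The margin code selects the edge blur sigma (0.5, 1.5,
3 px at 64 px; circumscribed sharpest), the density code the
lesion-over-background contrast (0.18, 0.32, 0.48), and the background is
smoothed correlated noise (sd 0.04). The mask is the *pre-blur* lesion
support: margin blur affects the image, never the ROI, mirroring
radiologist-drawn outlines that trace the lesion regardless of edge
conspicuity. Rasterization can shear a sub-pixel spicule tip off the
support, so the mask keeps its dominant connected component — ROIs are
single outlines by construction. Patches are written as 8-bit PNG pairs
(the quantization bound, 1/510, sits far below the background noise).

The label model is `P(malignant) = plogis(-9 + 4.5·shape + 4.5·margin +
3·micro + 3·spic + 3·density)` with uniform descriptor marginals. These
defaults were chosen by simulating the label model alone: they give ~50%
malignant prevalence (the clinical series this emulates was 50.9% / 49.1%)
and a descriptor-ceiling AUC of ~0.95, matching the strong
descriptor–malignancy association of the BI-RADS lexicon (and the ~0.95
validation AUC regime of the real-data pipeline). Every case draws its RNG
stream from a hash of (seed, case index), so datasets are reproducible and
cases are independent.

What the phantom does *not* emulate: X-ray physics, breast-density
(BI-RADS a–d) background structure, calcifications, inter-view geometric
consistency (views are i.i.d. re-renders, since only descriptor sharing
across views matters to the pipeline), and the intensity statistics of any
particular detector. Tests passing on the phantom demonstrate that the
pipeline recovers descriptor-driven signal under controlled conditions —
not that it reaches any particular performance on clinical images.

## Observer-study analytics

`roc_from_poms()` builds the ROC by sweeping the ranked unique POMs as
thresholds (cases at or above threshold called malignant) and integrates by
the trapezoidal rule; tied scores receive half credit, so the AUC equals
the Mann–Whitney statistic exactly. `reader_average_auc()` enforces the
fully crossed MRMC design (every reader scores every case) and averages
per-reader AUCs arithmetically. `auc_difference_test()` estimates the
aided-minus-unaided difference of reader-averaged AUCs with a case-level
bootstrap (readers fixed, cases resampled with replacement, both sessions
recomputed on the same resample), a percentile interval and a two-sided
bootstrap p-value. This is deliberately *not* the iMRMC
(Obuchowski–Rockette/Gallas) variance-component machinery: that method's
exact construction is out of scope here, so its published p-values are not
reproduction targets of this package.

`confusion_from_rates()` inverts printed sensitivity/specificity to integer
confusion counts given the class sizes (29 benign, 22 malignant in the
packaged observer tables), asserting the implied integer is within half a
count; a cell whose printed rate sits more than 0.001 from every integer
count is flagged as a probable typo rather than silently corrected (one
such cell exists in the packaged tables: reader 5's aided sensitivity,
printed 0.901 where the implied count gives 0.909). The 0.001 comparison
tolerance throughout absorbs truncated rounding in printed tables.
BI-RADS changes are counted on the ordinal scale 1 < 2 < 3 < 4 < 4a < 4b
< 4c < 5 (plain 4 accepted, placed between 3 and 4a); a changed case is
"closer to biopsy" when it moved toward the recall end (≥ 4) for malignant
truth or toward ≤ 3 for benign truth — an operationalization via the
BI-RADS 4+ biopsy-recommendation convention. Diagnosis times are compared
per reader with a two-sided paired t-test; reported means use half-up
rounding to 2 decimals (3 for rates), matching clinical-table conventions.

## Numerical and design notes

* POM is stored as percent (0–100) in reader records, as collected, and
  normalized to [0, 1] internally.
* `round_half_up()` is used for all reported values; base R's
  round-half-even would disagree with printed tables on exact .5 cases.
* Stepwise selection guards against non-finite F statistics (aliased
  columns get p = 1) and caps iterations at 10·p as a cycling guard;
  `p_enter <= p_remove` is enforced to prevent enter/remove loops.
* Empty stepwise selections (possible on degenerate folds) fall back to
  the single highest-variance feature so the member LDA remains defined.
* The bootstrap redraws a resample until both classes are present; with
  51-case sets this is a rare event.
* Problem sizes in the test suite: the end-to-end check trains the
  desk-scale profile on 300 phantom cases (K = 5) and evaluates the fused
  POM on 100 held-out cases; module tests use 32-px networks and a few
  dozen cases.

## Known limitations

* The full 288-px, width-1 network is implemented but CPU training at that
  scale is slow; the desk profile is the supported day-to-day
  configuration.
* Training reproducibility is exact for a fixed platform/BLAS; across
  different BLAS builds, floating-point reassociation can change trained
  weights (inference on fixed weights is stable).
* The phantom's descriptor-visibility calibration is for 64 px and above;
  at 32 px microlobulation approaches the pixel scale and is only weakly
  expressed.
* `parse_report_line()` is a closed-vocabulary parser by design; real
  radiology reports need upstream normalization.
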
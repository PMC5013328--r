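---
title: "Automated tubule nuclei quantification: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated tubule nuclei quantification: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubulequant)
library(dplyr)
```

## The problem

Tubule formation is one of the three components of the Bloom–Richardson
(BR) grade of breast cancer: well-differentiated, less aggressive tumours
retain glandular structures — rings of epithelial nuclei around a white
lumen — while aggressive tumours lose them. Gene-expression recurrence
assays such as Oncotype DX (ODX) stratify ER+ tumours into low (< 18),
intermediate (18–30) and high (> 30) risk, but are expensive and tissue
destructive, whereas the H&E slide is always available. `tubulequant`
implements an automated, slide-level *tubule formation indicator* (TFI):

\[
\mathrm{TFI} = \frac{\#\{\text{nuclei classified as tubule nuclei}\}}
                    {\#\{\text{all detected nuclei}\}},
\]

averaged per slide over its high power fields (HPFs), and the statistical
machinery to relate it to ODX/BR risk groups.

The pipeline has four stages:

1. **Nuclei detection.** The blue ratio transform
   \(BR = \frac{100\,B}{1+R+G}\cdot\frac{256}{1+R+G+B}\)
   amplifies hematoxylin-stained (blue/purple) nuclei against the
   eosin-pink stroma. A global Otsu threshold on the binned BR image,
   a morphological opening with a small disc, and 8-connected component
   centroids yield nucleus candidates. This is deliberately a *rough*
   estimator — touching nuclei merge into one candidate — but it is
   representative of the nuclei population in TFI terms, which is all the
   downstream statistic needs (a property the test-suite checks).
2. **Patch classification.** A 64×64 RGB patch around each candidate
   (0.5 µm/pixel, so a 32 µm context window) is classified tubule /
   non-tubule by a small convolutional network: conv–ReLU–max-pool blocks
   followed by two fully connected layers and a 2-way softmax. A patch is
   called a tubule nucleus when its probability strictly exceeds 0.5.
3. **Slide aggregation.** Per-field TFIs are averaged per slide over at
   most 50 fields; when more are available the lowest-TFI fields are kept,
   which guards against fields with unusually many detected tubule nuclei.
4. **Risk statistics.** Welch (unequal-variance) t-tests compare per-slide
   mean TFI between six group pairs (high/low/intermediate ODX and the
   combined ODX+BR groups HH, LL and their complements), and an ROC curve
   classifies "low risk" by thresholding the mean TFI (low-ODX positive),
   with the operating point closest to (0, 1).

## The synthetic cohort generator

The cohorts on which such pipelines were originally developed (whole slide
images with pathologist tubule delineations) are not distributable, so the
package ships a first-class synthetic generator that emulates the relevant
image structure:

- a tubule is a white, slightly elliptical lumen surrounded by a ring of
  `nuclei_per_tubule_ring` (default 8) dark elliptical nuclei, the whole
  structure enclosed by a polygon annotation (the "pathologist
  delineation");
- non-tubule nuclei are scattered outside every tubule polygon;
- colours are H&E-like with per-nucleus Gaussian jitter and low-amplitude
  background texture noise — enough structure that the blue ratio
  transform and Otsu threshold are exercised non-trivially.

Placement is rejection sampling with a bounded number of attempts (default
1000); an impossible request raises an explicit placement error. Nucleus
separation constraints can be disabled (`allow_overlap`) to study the
merged-component behaviour of the detector.

Key scale choices, made once:

- **Field size 224×224 px** at 0.5 µm/px. Nothing in the method depends on
  the absolute field size (the TFI is a ratio); small fields keep
  cohort-scale simulation cheap on one CPU.
- **Nucleus major semi-axis 4.5–5.5 px, axis ratio 0.6–0.8**, i.e. nuclei
  4.5–5.5 µm across — realistic for epithelial nuclei at this resolution,
  and wide enough to survive a radius-2 opening (a morphological opening
  erases any object thinner than its structuring element, so nuclei much
  under 5 px wide would be physically undetectable by design).
- **30 free nuclei per field.** Real HPFs are denser, but the TFI is a
  ratio and its per-slide averages stabilise quickly; density mainly
  trades run time against per-field variance.
- **Tubule counts** per field are truncated-Poisson (cap 4). The rate is
  *calibrated*: `calibrate_tubule_lambda()` solves
  \(E\!\left[\frac{mT}{mT+F}\right] = \text{target}\) for λ, so group
  densities can be pinned to the slide-level group means the study design
  expects — 0.029 for high-ODX/high-grade-like (HH) and 0.126 for
  low-ODX/low-grade-like (LL) slides. ODX scores and BR grades are sampled
  from value sets validated against the group rules at configuration time,
  so every HH slide has ODX > 30 and BR > 7 by construction.
- One patient per slide (a documented simplification; the fold-splitting
  code treats patients as first-class regardless).

What the generator does **not** emulate: stain variability between slides,
nuclear pleomorphism, mitoses, stromal texture classes, overlapping tissue
layers, or lumen-like artefacts (vessels, fat). Passing tests therefore
demonstrate the pipeline's internal correctness and its statistical
machinery, not real-data classification performance — on real tissue the
classifier's task is far harder (per-fold F-scores around 0.6 are typical on real cohorts,
rather than the ≈0.95 reached on this separable synthetic task).

## Detection: numerical choices

- **Otsu on a binned histogram** (default 256 bins over the observed
  range); the returned threshold is the bin boundary maximising the
  between-class variance, and foreground is *strictly above* it, so a
  constant image yields no foreground rather than one whole-image
  "nucleus". The implementation is closed-form (cumulative sums); an
  exhaustive-search oracle in the tests guarantees equivalence.
- **Unimodality guard.** On a field with no nuclei at all, Otsu happily
  splits the background noise and the opening can leave a few spurious
  blobs. `detect_nuclei()` therefore requires the standard Otsu
  effectiveness coefficient (between-class variance / total variance) to
  reach `min_bimodality` (default 0.8) before accepting any foreground:
  pure Gaussian noise yields ≈ 0.64 regardless of its variance, while any
  field containing stained nuclei scores ≈ 0.95+. This is the package's
  own addition, exposed as an ordinary parameter.
- **Opening radius 2 px, minimum component area 15 px** at 0.5 µm/px:
  a ~6 µm nucleus survives comfortably, isolated specks do not. Both are
  free parameters of `detection_params()`.
- **8-connected components**; the centroid is the unweighted mean of the
  member pixel coordinates; candidates are sorted by (row, col) and those
  near the border are kept (patch extraction mirror-pads, so border
  nuclei stay usable and the TFI denominator is not biased at field
  edges).

## Patches and labels

- Window convention: rows `[r−32, r+32)` after rounding the centroid
  half-up; mirror reflection (edge pixel duplicated) fills out-of-bounds
  pixels. This is the single source of truth for patch geometry.
- A candidate is labelled *tubule* iff its centroid lies inside **or on
  the boundary of** a tubule polygon — boundary-inclusive because the
  delineations enclose whole tubules including the nuclear ring, so a
  centroid exactly on the line belongs to the tubule.
- Cross-validation folds are split **at the patient level**: patients are
  permuted by seed and dealt round-robin, fold sizes differ by at most
  one, and every patch inherits its patient's fold. This is what makes
  held-out metrics honest in histopathology, where two fields of one
  patient are far more alike than fields of different patients.

## The classifier

The architecture is fully configurable (`cnn_architecture()`): a list of
(filters, kernel, pool) conv blocks — valid convolution, stride 1, ReLU,
non-overlapping max pooling — then two fully connected layers ending in a
2-way softmax. The default is three 3×3 blocks with 6/12/24 filters, pool
2, and a 32-unit hidden layer (≈ 31k parameters): on the nearly separable
synthetic task wider nets buy nothing, and this size trains on a whole
cohort's patches in seconds on one CPU. Training hyper-parameters
(`train_config()`): Adam, learning rate 1e-3, batch 32, 3 epochs, at most
1500 training patches (uniform subsample), minority oversampling per epoch
(tubule nuclei are the minority in any realistic field), and lossless
flip augmentation. All stochastic steps are seeded; fixed seed and data
give identical weights on one device. The forward/backward pass is
RcppArmadillo (im2col + GEMM) and is verified against central finite
differences in the tests.

Degenerate inputs: training with a single-class patch set is an error, not
a silent fit; probabilities outside [0, 1] passed to `classify_tubule()`
are an error; the decision rule is strict (`p > threshold`), so exactly
0.5 is non-tubule.

## Evaluation and risk statistics

- Metrics treat tubule as the positive class; 0/0 ratios are reported as 0
  with a warning. Fold summaries use the arithmetic mean and the sample
  (n−1) standard deviation — the convention that reproduces the reference
  per-fold table's summary row exactly after two-decimal rounding
  (population standard deviation does not).
- Welch t-tests are two-sided (the conservative reading when only
  significance levels are reported), with the Welch–Satterthwaite degrees
  of freedom and a 95% CI on the mean difference (Student quantiles at the
  Welch df). Implemented via `stats::t.test`; the tests cross-check the
  closed form.
- The ROC sweeps thresholds over the observed distinct TFIs plus the
  [0, 1] endpoints — equivalent to the continuous curve, and the
  trapezoidal AUC then equals the Mann–Whitney concordance probability
  exactly (tie handling included; a (0,0) anchor is prepended when a TFI
  ties the top threshold). The reported operating threshold minimises the
  Euclidean distance to (0, 1); ties go to the larger threshold. The
  default comparison is HH vs LL with low risk as the positive class;
  the full low-vs-high ODX comparison is available via `roc_groups`.
- Fields with zero detected nuclei are excluded from a slide's TFI list
  with a message — a 0/0 TFI carries no information and silently calling
  it 0 would bias slides downward.
- ODX boundaries are exact: 18 and 30 are intermediate; BR 6 and 7 belong
  to neither LL nor HH.

## Problem sizes used by the tests and the acceptance script

The shipped checks run the full pipeline at a deliberate desk scale:
evaluation cohorts of 15 HH-like + 15 LL-like slides with 10 fields each
(224 px fields), training cohorts of 8–10 tubule-rich slides with 4 fields
each, ten seeded end-to-end replicates for the recovery check, and 30
fields for detection quality. At this scale the HH-vs-LL Welch test and
the TFI ROC recover the built-in group separation essentially always
(p ≪ 0.01, AUC ≈ 0.95–1.0), detection recall/precision sit near 0.99, and
cross-validated tubule F-scores around 0.95.

## Known limitations

- The detector does not split touching nuclei (no watershed); overlap
  produces one merged candidate by design.
- The TFI depends on the classifier's operating point; the 0.5 threshold
  is used throughout, matching the method being emulated, and no
  calibration analysis is performed.
- Synthetic imagery is far easier than real H&E tissue; absolute
  classifier metrics here are upper bounds, not forecasts.
- The generator draws each field independently; it does not model
  within-slide spatial correlation beyond the per-slide tubule rate.
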
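# tubulequant

Automated quantification of tubule formation in H&E-stained breast-cancer
high power fields, and its correlation with Oncotype DX (ODX) risk
categories and Bloom–Richardson (BR) grade.

Tubule formation — rings of epithelial nuclei around a white lumen — is
the component of the BR grade that aggressive ER+ breast cancers lose.
`tubulequant` computes a slide-level **tubule formation indicator**

```
TFI = (# nuclei classified as tubule nuclei) / (# all detected nuclei)
```

by:

1. detecting nuclei candidates with the **blue ratio transform**
   `BR = (100·B/(1+R+G)) · (256/(1+R+G+B))`, an Otsu threshold,
   a morphological opening and 8-connected component centroids;
2. classifying a 64×64 RGB patch around each candidate as *tubule* /
   *non-tubule* with a small **convolutional neural network**
   (conv–ReLU–max-pool blocks + two fully connected layers, 2-way
   softmax; a patch is a tubule nucleus when its probability exceeds
   0.5), trained with patient-level 5-fold cross-validation;
3. averaging per-field TFIs per slide (at most the 50 lowest-TFI fields);
4. comparing slide groups (high/low/intermediate ODX; the combined
   ODX>30 & BR>7 "HH" and ODX<18 & BR<6 "LL" groups and their
   complements) with **Welch t-tests**, and classifying "low risk" by
   thresholding the mean TFI in an **ROC analysis** (AUC = Mann–Whitney
   concordance; operating point closest to (0,1)).

Because real annotated WSI cohorts are not distributable, the package
includes a first-class synthetic H&E field generator: white elliptical
lumina ringed by dark nuclei (with polygon "delineations"), scattered
non-tubule nuclei, H&E-like colours with noise, and whole cohorts whose
per-group tubule density is calibrated so the expected per-field TFI hits
a requested target (defaults: 0.029 for HH-like, 0.126 for LL-like
slides). Everything is deterministic given seeds.

## Worked example

Generate a small two-group cohort, train the patch classifier on an
annotated tubule-rich cohort, quantify every field and run the risk
analysis:

```r
library(tubulequant)

train_cohort <- generate_cohort(cohort_config(
  groups = list(LL = group_spec(8, tubule_lambda = 1.2,
                                odx_values = 2:17, br_values = 3:5)),
  hpfs_per_wsi = 4, seed = 101))

eval_cohort <- generate_cohort(default_cohort_config(
  n_hh = 8, n_ll = 8, hpfs_per_wsi = 6, seed = 202))

res <- run_tfi_pipeline(train_cohort, eval_cohort, seed = 1)
res$analysis
```

```
<tfi_analysis> 16 slides
# A tibble: 6 × 5
  comparison     n_a   n_b  p_value mean_difference
  <chr>        <int> <int>    <dbl>           <dbl>
1 H vs L           8     8 0.000791          -0.110
2 H vs L and I     8     8 0.000791          -0.110
3 H and I vs L     8     8 0.000791          -0.110
4 HH vs LL         8     8 0.000791          -0.110
5 LLc vs LL        8     8 0.000791          -0.110
6 HH vs HHc        8     8 0.000791          -0.110
<tfi_roc> AUC 0.984 (8 low vs 8 high); optimal threshold 0.0907 (FPR 0.00, TPR 0.88)
```

The cohort contains only HH and LL slides, so all six group comparisons
coincide here. HH-like slides (generated to a mean per-field TFI of
0.029) are cleanly separated from LL-like slides (0.126): the Welch test
on per-slide mean TFI gives p ≈ 8·10⁻⁴ with the high-risk group 0.11
lower on average, and thresholding the mean TFI at 0.09 classifies 15 of
the 16 slides correctly (AUC 0.98). `autoplot(res$analysis$roc)` draws
the curve; `plot_tfi_violin(res$analysis$wsi)` shows the per-group TFI
distributions; `glance(res$model)` summarises the fitted classifier.

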
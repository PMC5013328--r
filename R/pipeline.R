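#' Collect a labelled patch learning set from a synthetic cohort
#'
#' Streams every field of the cohort: detects nuclei candidates, labels
#' them against the field's tubule delineation (centroid-in-polygon) and
#' extracts their 64 x 64 patches. This mirrors the curation of a learning
#' set from pathologist-annotated fields.
#'
#' @param cohort a [generate_cohort()] result.
#' @param params a [detection_params()].
#' @return list with `patches` (`n x 64 x 64 x 3` array), `labels`
#'   (character) and `manifest` (tibble: `patch_id`, `field_id`, `wsi_id`,
#'   `patient_id`, `row`, `col`, `label`).
#' @export
collect_training_patches <- function(cohort, params = detection_params()) {
  patches <- list()
  manifest <- list()
  pid <- cohort$metadata$patient_id[match(cohort$fields$wsi_id,
                                          cohort$metadata$wsi_id)]
  for (i in seq_len(nrow(cohort$fields))) {
    fid <- cohort$fields$field_id[i]
    sf <- realize_field(cohort, fid)
    cand <- detect_nuclei(sf$field, params)
    if (nrow(cand) == 0) next
    cand <- label_candidates(cand, sf$annotation)
    patches[[fid]] <- extract_patches(sf$field, cand)
    manifest[[fid]] <- tibble(
      field_id = fid, wsi_id = cohort$fields$wsi_id[i], patient_id = pid[i],
      row = cand$row, col = cand$col, label = cand$label)
  }
  manifest <- dplyr::bind_rows(manifest)
  manifest <- dplyr::mutate(manifest,
                            patch_id = sprintf("p%06d", dplyr::row_number()),
                            .before = 1)
  n <- nrow(manifest)
  all <- array(0, dim = c(n, 64, 64, 3))
  at <- 1
  for (p in patches) {
    k <- dim(p)[1]
    if (k > 0) all[at:(at + k - 1), , , ] <- p
    at <- at + k
  }
  list(patches = all, labels = manifest$label, manifest = manifest)
}

#' Quantify tubule formation across a cohort
#'
#' Applies the full per-field pipeline to every field of a (synthetic)
#' cohort: nuclei detection, patch extraction, classifier probabilities,
#' thresholding at the model's decision threshold, and the per-field
#' tubule/total counts. Ground-truth counts are carried along for
#' validation of the detector and classifier.
#'
#' @param cohort a [generate_cohort()] result.
#' @param model a trained [build_model()] classifier.
#' @param params a [detection_params()].
#' @return a tibble with one row per field: `wsi_id`, `field_id`,
#'   `n_tubule`, `n_total` (detected and classified), plus ground truth
#'   `gt_n_tubule`, `gt_n_total`.
#' @export
quantify_cohort <- function(cohort, model, params = detection_params()) {
  purrr::map_dfr(seq_len(nrow(cohort$fields)), function(i) {
    fid <- cohort$fields$field_id[i]
    sf <- realize_field(cohort, fid)
    cand <- detect_nuclei(sf$field, params)
    n_tub <- 0L
    if (nrow(cand) > 0) {
      prob <- predict_tubule_prob(model, extract_patches(sf$field, cand))
      n_tub <- sum(classify_tubule(prob, model$decision_threshold) == "tubule")
    }
    tibble(wsi_id = cohort$fields$wsi_id[i], field_id = fid,
           n_tubule = n_tub, n_total = nrow(cand),
           gt_n_tubule = sum(sf$nuclei$is_tubule),
           gt_n_total = nrow(sf$nuclei))
  })
}

#' Slide-level risk analysis of per-field tubule counts
#'
#' Aggregates per-field counts to per-slide mean TFI (at most `cap`
#' lowest-TFI fields per slide), joins the cohort metadata, runs the six
#' group comparisons and the HH-vs-LL ROC (low-risk positive).
#'
#' @param metadata cohort metadata tibble (`wsi_id`, `odx_score`,
#'   `br_grade`, ...).
#' @param field_tfi per-field counts as from [quantify_cohort()].
#' @param cap per-slide field cap (default 50).
#' @param roc_groups which groups feed the ROC: `"HH_LL"` (default;
#'   low = LL, high = HH) or `"ODX"` (low = low-ODX, high = high-ODX).
#' @return a list of class `tfi_analysis`: `wsi` (per-slide tibble with
#'   metadata, memberships and `mean_tfi`), `comparisons` (six Welch
#'   t-tests) and `roc` (a `tfi_roc`).
#' @export
analyze_cohort <- function(metadata, field_tfi, cap = 50,
                           roc_groups = c("HH_LL", "ODX")) {
  roc_groups <- match.arg(roc_groups)
  wsi <- summarize_wsi_tfi(field_tfi, cap = cap) |>
    dplyr::inner_join(metadata, by = "wsi_id")
  wsi <- dplyr::bind_cols(wsi, assign_groups(wsi$odx_score, wsi$br_grade))
  comparisons <- run_group_comparisons(wsi)
  roc <- if (roc_groups == "HH_LL") {
    roc_from_tfi(low_tfis = wsi$mean_tfi[wsi$ll_group == "LL"],
                 high_tfis = wsi$mean_tfi[wsi$hh_group == "HH"])
  } else {
    roc_from_tfi(low_tfis = wsi$mean_tfi[wsi$odx_risk == "LOW_ODX"],
                 high_tfis = wsi$mean_tfi[wsi$odx_risk == "HIGH_ODX"])
  }
  structure(list(wsi = wsi, comparisons = comparisons, roc = roc),
            class = "tfi_analysis")
}

#' @export
print.tfi_analysis <- function(x, ...) {
  cat(sprintf("<tfi_analysis> %d slides\n", nrow(x$wsi)))
  print(dplyr::select(x$comparisons, "comparison", "n_a", "n_b",
                      "p_value", "mean_difference"))
  print(x$roc)
  invisible(x)
}

#' Train and apply the whole pipeline on synthetic cohorts
#'
#' Convenience wrapper for the complete experiment: curate a learning set
#' from an annotated training cohort, train the patch classifier, quantify
#' an independent evaluation cohort and run the risk analysis.
#'
#' @param train_cohort annotated cohort used for the learning set.
#' @param eval_cohort cohort on which TFI and risk statistics are computed.
#' @param arch a [cnn_architecture()].
#' @param cfg a [train_config()].
#' @param params a [detection_params()].
#' @param cap per-slide field cap.
#' @param seed seed for model initialisation.
#' @return a list: `model` (trained classifier), `field_tfi`
#'   (per-field counts) and `analysis` (a `tfi_analysis`).
#' @export
run_tfi_pipeline <- function(train_cohort, eval_cohort,
                             arch = cnn_architecture(),
                             cfg = train_config(),
                             params = detection_params(),
                             cap = 50, seed = 1L) {
  learn <- collect_training_patches(train_cohort, params)
  model <- build_model(arch, seed = seed)
  model <- train_classifier(model, learn$patches, learn$labels, cfg)
  field_tfi <- quantify_cohort(eval_cohort, model, params)
  analysis <- analyze_cohort(eval_cohort$metadata, field_tfi, cap = cap)
  list(model = model, field_tfi = field_tfi, analysis = analysis)
}
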
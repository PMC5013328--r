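#' Confusion counts with tubule as the positive class
#'
#' @param predicted,truth character vectors of `"tubule"` / `"non_tubule"`
#'   labels (or logical vectors, `TRUE` = tubule) of equal length.
#' @return a one-row tibble with columns `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    abort("`predicted` and `truth` must have equal length")
  }
  p <- label_to_int(predicted) == 1L
  t <- label_to_int(truth) == 1L
  tibble(tp = sum(p & t), fp = sum(p & !t),
         fn = sum(!p & t), tn = sum(!p & !t))
}

#' Classification metrics for the tubule class
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)` (sensitivity),
#' `specificity = tn/(tn+fp)` and `f_score = 2PR/(P+R)`. Undefined 0/0
#' ratios are reported as 0 with a warning.
#'
#' @param counts a one-row tibble (or named list) with `tp`, `fp`, `fn`,
#'   `tn`, as from [confusion_counts()].
#' @return a one-row tibble with `f_score`, `precision`, `recall`,
#'   `specificity`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  if (any(c(tp, fp, fn, tn) < 0)) abort("confusion counts must be non-negative")
  ratio0 <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s is 0/0; reporting 0", what))
      return(0)
    }
    num / den
  }
  precision <- ratio0(tp, tp + fp, "precision")
  recall <- ratio0(tp, tp + fn, "recall")
  specificity <- ratio0(tn, tn + fp, "specificity")
  f_score <- if (precision + recall == 0) {
    warn("f_score is 0/0; reporting 0")
    0
  } else 2 * precision * recall / (precision + recall)
  tibble(f_score = f_score, precision = precision, recall = recall,
         specificity = specificity)
}

#' Aggregate per-fold metrics
#'
#' Arithmetic mean and sample (n-1) standard deviation of each metric
#' across folds. Values are kept at full precision; any rounding (the
#' conventional two decimals) is presentation only.
#'
#' @param fold_metrics tibble with one row per fold and numeric metric
#'   columns (e.g. `f_score`, `precision`, `recall`, `specificity`).
#' @return a tibble with columns `metric`, `mean`, `sd`.
#' @export
aggregate_folds <- function(fold_metrics) {
  num <- dplyr::select(fold_metrics, dplyr::where(is.numeric))
  num <- dplyr::select(num, -dplyr::any_of(c("fold", "n_test")))
  if (nrow(num) < 2) abort("at least two folds are needed for a standard deviation")
  tidyr::pivot_longer(num, dplyr::everything(),
                      names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value)) |>
    dplyr::mutate(metric = factor(.data$metric, levels = names(num))) |>
    dplyr::arrange(.data$metric) |>
    dplyr::mutate(metric = as.character(.data$metric))
}

#' Patient-level cross-validated evaluation of the patch classifier
#'
#' Splits patients into `k` folds with [split_folds_by_patient()], then for
#' each fold trains a fresh classifier on the other folds' patches and
#' evaluates tubule-class metrics on the held-out fold. Because the split
#' is at the patient level, no patient contributes patches to both sides.
#'
#' @param patches `n x 64 x 64 x 3` array.
#' @param labels character labels, length n.
#' @param patient_ids character, length n.
#' @param k number of folds.
#' @param arch a [cnn_architecture()].
#' @param cfg a [train_config()].
#' @param seed seed for the fold split and per-fold model initialisation.
#' @return a list of class `crossval_result`: `fold_metrics` (per-fold
#'   tibble with `fold`, `n_test` and the four metrics), `summary`
#'   (from [aggregate_folds()]) and `folds` (the patient assignment).
#' @export
crossval_classifier <- function(patches, labels, patient_ids, k = 5,
                                arch = cnn_architecture(),
                                cfg = train_config(), seed = 1L) {
  folds <- split_folds_by_patient(patient_ids, k = k, seed = seed)
  fold_of <- folds$fold[match(patient_ids, folds$patient_id)]
  rows <- purrr::map(seq_len(k), function(f) {
    test <- fold_of == f
    model <- build_model(arch, seed = seed + f)
    fit_cfg <- cfg
    fit_cfg$seed <- cfg$seed + f
    model <- train_classifier(model,
                              patches[!test, , , , drop = FALSE],
                              labels[!test], fit_cfg)
    prob <- predict_tubule_prob(model, patches[test, , , , drop = FALSE])
    pred <- classify_tubule(prob, model$decision_threshold)
    cc <- confusion_counts(pred, labels[test])
    dplyr::bind_cols(tibble(fold = f, n_test = sum(test)),
                     suppressWarnings(compute_metrics(cc)), cc)
  })
  fold_metrics <- dplyr::bind_rows(rows)
  structure(
    list(fold_metrics = fold_metrics,
         summary = aggregate_folds(
           dplyr::select(fold_metrics, dplyr::all_of(
             c("f_score", "precision", "recall", "specificity")))),
         folds = folds),
    class = "crossval_result"
  )
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<crossval_result> %d folds\n", nrow(x$fold_metrics)))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.crossval_result <- function(x, ...) x$fold_metrics

#' @export
glance.crossval_result <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean", "sd"))
}
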
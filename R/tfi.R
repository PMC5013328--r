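#' Tubule formation indicator
#'
#' The TFI of a field is the ratio of tubule nuclei to all detected nuclei.
#' Fields with zero detected nuclei carry no information and must be
#' excluded upstream; passing `n_total = 0` is an error, not a silent 0.
#'
#' @param n_tubule_nuclei,n_total_nuclei non-negative integers (vectorised),
#'   with `n_tubule_nuclei <= n_total_nuclei` and `n_total_nuclei > 0`.
#' @return numeric vector in `[0, 1]`.
#' @export
compute_tfi <- function(n_tubule_nuclei, n_total_nuclei) {
  if (any(n_total_nuclei == 0)) {
    abort("field with zero detected nuclei: exclude it before computing TFI",
          class = "tubulequant_empty_field")
  }
  if (any(n_tubule_nuclei < 0) || any(n_tubule_nuclei > n_total_nuclei)) {
    abort("need 0 <= n_tubule_nuclei <= n_total_nuclei")
  }
  n_tubule_nuclei / n_total_nuclei
}

#' Select the lowest-TFI fields of a slide
#'
#' At most `cap` fields per slide enter the slide mean; when more are
#' available, the `cap` fields with the smallest TFI are kept (this guards
#' against fields with unusually many detected tubule nuclei). Ties are
#' broken by original field order (stable sort).
#'
#' @param hpf_tfis numeric vector of per-field TFIs (non-empty).
#' @param cap maximum number of fields (default 50).
#' @return integer indices into `hpf_tfis`, in increasing index order.
#' @export
select_hpfs <- function(hpf_tfis, cap = 50) {
  if (length(hpf_tfis) == 0) abort("`hpf_tfis` must be non-empty")
  if (cap < 1) abort("`cap` must be at least 1")
  if (length(hpf_tfis) <= cap) return(seq_along(hpf_tfis))
  sort(order(hpf_tfis)[seq_len(cap)])
}

#' Mean TFI of one slide
#'
#' Arithmetic mean over the selected (at most `cap` lowest-TFI) fields.
#'
#' @param hpf_tfis numeric vector of per-field TFIs.
#' @param cap field cap per slide.
#' @return scalar mean TFI.
#' @export
mean_tfi_per_wsi <- function(hpf_tfis, cap = 50) {
  mean(hpf_tfis[select_hpfs(hpf_tfis, cap)])
}

#' Per-slide TFI summary from a per-field table
#'
#' Excludes fields with zero detected nuclei (with a message), computes the
#' per-field TFI, applies the per-slide field cap and returns one row per
#' slide.
#'
#' @param field_tfi tibble with columns `wsi_id`, `field_id`, `n_tubule`,
#'   `n_total`.
#' @param cap per-slide field cap (default 50).
#' @return tibble with `wsi_id`, `n_fields`, `n_selected`, `mean_tfi`.
#' @export
summarize_wsi_tfi <- function(field_tfi, cap = 50) {
  drop <- field_tfi$n_total == 0
  if (any(drop)) {
    inform(sprintf("excluding %d field(s) with zero detected nuclei", sum(drop)))
    field_tfi <- field_tfi[!drop, ]
  }
  if (nrow(field_tfi) == 0) abort("no fields with detected nuclei remain")
  field_tfi |>
    dplyr::mutate(tfi = compute_tfi(.data$n_tubule, .data$n_total)) |>
    dplyr::group_by(.data$wsi_id) |>
    dplyr::summarise(n_fields = dplyr::n(),
                     n_selected = length(select_hpfs(.data$tfi, cap)),
                     mean_tfi = mean_tfi_per_wsi(.data$tfi, cap))
}

#' Assign ODX / BR risk-group memberships
#'
#' Groups follow the usual cut-offs, all boundaries handled exactly:
#' ODX > 30 is high risk, ODX < 18 low, `18 <= ODX <= 30` intermediate;
#' `HH` requires both ODX > 30 and BR > 7 (so BR = 7 is not HH), `LL` both
#' ODX < 18 and BR < 6; `HHC` and `LLC` are the complements within the
#' cohort. Every slide gets exactly one label from each of the three
#' partitions.
#'
#' @param odx_score numeric ODX recurrence scores (>= 0), vectorised.
#' @param br_grade integer Bloom-Richardson grades in 3..9.
#' @return a tibble with columns `odx_risk` (`HIGH_ODX` / `INTERMEDIATE_ODX`
#'   / `LOW_ODX`), `hh_group` (`HH` / `HHC`) and `ll_group` (`LL` / `LLC`).
#' @export
assign_groups <- function(odx_score, br_grade) {
  if (any(odx_score < 0)) abort("ODX scores must be non-negative")
  if (any(br_grade < 3 | br_grade > 9)) {
    abort("BR grades must lie in the Bloom-Richardson range 3..9")
  }
  tibble(
    odx_risk = dplyr::case_when(
      odx_score > 30 ~ "HIGH_ODX",
      odx_score < 18 ~ "LOW_ODX",
      .default = "INTERMEDIATE_ODX"),
    hh_group = ifelse(odx_score > 30 & br_grade > 7, "HH", "HHC"),
    ll_group = ifelse(odx_score < 18 & br_grade < 6, "LL", "LLC")
  )
}

#' Welch two-sample t-test
#'
#' Two-sided t-test under unequal variances (Welch-Satterthwaite degrees of
#' freedom), reporting the mean difference `mean(a) - mean(b)` with its 95%
#' confidence interval.
#'
#' @param a,b numeric samples, each with at least two values.
#' @return a one-row tibble with `t_statistic`, `df`, `p_value`,
#'   `mean_difference`, `ci_low`, `ci_high`.
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort("each sample needs at least two values",
          class = "tubulequant_undersized_group")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, conf.level = 0.95)
  tibble(t_statistic = unname(tt$statistic),
         df = unname(tt$parameter),
         p_value = tt$p.value,
         mean_difference = mean(a) - mean(b),
         ci_low = tt$conf.int[1],
         ci_high = tt$conf.int[2])
}

#' The six standard risk-group comparisons
#'
#' Welch t-tests of per-slide mean TFI between: high vs low ODX; high vs
#' low-plus-intermediate; high-plus-intermediate vs low; HH vs LL; LLC vs
#' LL; HH vs HHC. A comparison whose groups have fewer than two slides is
#' flagged (`ok = FALSE`, statistics `NA`) while the others still run.
#'
#' @param wsi tibble with columns `mean_tfi`, `odx_score`, `br_grade`
#'   (one row per slide), e.g. [summarize_wsi_tfi()] joined to cohort
#'   metadata.
#' @return a tibble with one row per comparison: `comparison`, `group_a`,
#'   `group_b`, `n_a`, `n_b`, `ok` and the [welch_ttest()] columns.
#' @export
run_group_comparisons <- function(wsi) {
  g <- assign_groups(wsi$odx_score, wsi$br_grade)
  tfi <- wsi$mean_tfi
  sets <- list(
    H = tfi[g$odx_risk == "HIGH_ODX"],
    I = tfi[g$odx_risk == "INTERMEDIATE_ODX"],
    L = tfi[g$odx_risk == "LOW_ODX"],
    HH = tfi[g$hh_group == "HH"],
    HHC = tfi[g$hh_group == "HHC"],
    LL = tfi[g$ll_group == "LL"],
    LLC = tfi[g$ll_group == "LLC"])
  comparisons <- list(
    list(name = "H vs L", a = sets$H, b = sets$L,
         ga = "HIGH_ODX", gb = "LOW_ODX"),
    list(name = "H vs L and I", a = sets$H, b = c(sets$L, sets$I),
         ga = "HIGH_ODX", gb = "LOW+INT_ODX"),
    list(name = "H and I vs L", a = c(sets$H, sets$I), b = sets$L,
         ga = "HIGH+INT_ODX", gb = "LOW_ODX"),
    list(name = "HH vs LL", a = sets$HH, b = sets$LL, ga = "HH", gb = "LL"),
    list(name = "LLc vs LL", a = sets$LLC, b = sets$LL, ga = "LLC", gb = "LL"),
    list(name = "HH vs HHc", a = sets$HH, b = sets$HHC, ga = "HH", gb = "HHC"))
  purrr::map_dfr(comparisons, function(cmp) {
    base <- tibble(comparison = cmp$name, group_a = cmp$ga, group_b = cmp$gb,
                   n_a = length(cmp$a), n_b = length(cmp$b))
    if (length(cmp$a) < 2 || length(cmp$b) < 2) {
      warn(sprintf("comparison '%s' has an undersized group; skipped", cmp$name))
      return(dplyr::bind_cols(base, tibble(
        ok = FALSE, t_statistic = NA_real_, df = NA_real_, p_value = NA_real_,
        mean_difference = NA_real_, ci_low = NA_real_, ci_high = NA_real_)))
    }
    dplyr::bind_cols(base, tibble(ok = TRUE), welch_ttest(cmp$a, cmp$b))
  })
}

#' ROC analysis of the slide-level TFI
#'
#' Each slide whose mean TFI is at or above a threshold is classified as
#' low-risk (low ODX is the positive class: tubule formation is preserved
#' in low-risk disease). Sweeping the threshold over all observed values
#' plus the `[0, 1]` endpoints traces the ROC curve exactly; the AUC is the
#' trapezoidal area, which equals the Mann-Whitney concordance probability.
#' The operating threshold reported is the one whose `(FPR, TPR)` point is
#' closest (Euclidean) to the ideal corner `(0, 1)`; ties go to the larger
#' threshold.
#'
#' @param low_tfis per-slide mean TFIs of the low-risk (positive) group.
#' @param high_tfis per-slide mean TFIs of the high-risk (negative) group.
#' @return an object of class `tfi_roc`: list with `points` (tibble
#'   `threshold`, `fpr`, `tpr`, descending threshold), `auc`,
#'   `optimal_threshold`, `n_low`, `n_high`.
#' @export
roc_from_tfi <- function(low_tfis, high_tfis) {
  if (length(low_tfis) == 0 || length(high_tfis) == 0) {
    abort("both groups must be non-empty")
  }
  vals <- c(low_tfis, high_tfis)
  if (any(vals < 0 | vals > 1)) abort("TFIs must lie in [0, 1]")
  thresholds <- sort(unique(c(0, 1, vals)), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) mean(low_tfis >= t), 0)
  fpr <- vapply(thresholds, function(t) mean(high_tfis >= t), 0)
  if (tpr[1] > 0 || fpr[1] > 0) {
    # some TFI sits at the top threshold; anchor the curve at (0, 0)
    thresholds <- c(thresholds[1], thresholds)
    tpr <- c(0, tpr)
    fpr <- c(0, fpr)
  }
  points <- tibble(threshold = thresholds, fpr = fpr, tpr = tpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  d2 <- fpr^2 + (1 - tpr)^2
  best <- which.min(d2)  # first index = largest threshold on ties
  structure(
    list(points = points, auc = auc,
         optimal_threshold = thresholds[best],
         optimal_point = c(fpr = fpr[best], tpr = tpr[best]),
         n_low = length(low_tfis), n_high = length(high_tfis)),
    class = "tfi_roc"
  )
}

#' @export
print.tfi_roc <- function(x, ...) {
  cat(sprintf(
    "<tfi_roc> AUC %.3f (%d low vs %d high); optimal threshold %.4f (FPR %.2f, TPR %.2f)\n",
    x$auc, x$n_low, x$n_high, x$optimal_threshold,
    x$optimal_point["fpr"], x$optimal_point["tpr"]))
  invisible(x)
}

#' @export
tidy.tfi_roc <- function(x, ...) x$points

#' @export
glance.tfi_roc <- function(x, ...) {
  tibble(auc = x$auc, optimal_threshold = x$optimal_threshold,
         n_low = x$n_low, n_high = x$n_high)
}
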
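# Shared fixtures, built in code.

# a small tubule-rich training cohort for classifier tests; cached per session
tubule_rich_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cc <- cohort_config(
        groups = list(LL = group_spec(10, tubule_lambda = 1.2,
                                      odx_values = 2:17, br_values = 3:5)),
        hpfs_per_wsi = 4, seed = 4201)
      cache <<- generate_cohort(cc)
    }
    cache
  }
})

# labelled patches from the tubule-rich cohort; cached per session
tubule_patch_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- collect_training_patches(tubule_rich_cohort())
    cache
  }
})

# brute-force Otsu: exhaustive search over all histogram bin boundaries
# maximising the between-class variance of the binned values
otsu_bruteforce <- function(values, bins = 256) {
  v <- as.numeric(values)
  edges <- seq(min(v), max(v), length.out = bins + 1)
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2
  bin <- findInterval(v, edges, rightmost.closed = TRUE)
  x <- mids[bin]                       # binned representative values
  best_sigma <- -Inf
  best_thr <- NA_real_
  for (k in 1:(bins - 1)) {
    thr <- edges[k + 1]
    lo <- x[bin <= k]
    hi <- x[bin > k]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(x)
    sigma <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sigma > best_sigma) {
      best_sigma <- sigma
      best_thr <- thr
    }
  }
  best_thr
}

# Mann-Whitney pair-counting AUC oracle (positive = low-risk, higher TFI)
auc_paircount <- function(low, high) {
  conc <- 0
  for (l in low) for (h in high) {
    conc <- conc + (l > h) + 0.5 * (l == h)
  }
  conc / (length(low) * length(high))
}
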
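test_that("TFI is a guarded ratio", {
  expect_equal(compute_tfi(0, 100), 0)
  expect_equal(compute_tfi(100, 100), 1)
  expect_equal(compute_tfi(12, 96), 0.125)
  expect_equal(compute_tfi(c(1, 2), c(4, 8)), c(0.25, 0.25))
  expect_error(compute_tfi(0, 0), class = "tubulequant_empty_field")
  expect_error(compute_tfi(5, 4), "<=")
})

test_that("field selection keeps the lowest-TFI fields with stable ties", {
  expect_equal(select_hpfs(runif(30), cap = 50), 1:30)

  set.seed(5)
  tfis <- sample(seq(0, 1, length.out = 60))
  sel <- select_hpfs(tfis, cap = 50)
  expect_length(sel, 50)
  expect_setequal(tfis[sel], sort(tfis)[1:50])   # sort oracle
  expect_equal(mean_tfi_per_wsi(tfis, cap = 50), mean(sort(tfis)[1:50]))

  ties <- rep(0.3, 60)
  expect_equal(select_hpfs(ties, cap = 50), 1:50)

  expect_equal(mean_tfi_per_wsi(0.2), 0.2)
  expect_equal(mean_tfi_per_wsi(c(0.1, 0.2, 0.3), cap = 3), 0.2)
  expect_error(select_hpfs(numeric(0)), "non-empty")
})

test_that("per-slide summary drops empty fields and applies the cap", {
  ft <- tibble::tibble(
    wsi_id = c(rep("w1", 3), rep("w2", 2)),
    field_id = sprintf("f%d", 1:5),
    n_tubule = c(1, 2, 0, 0, 3),
    n_total = c(10, 10, 0, 10, 10))
  expect_message(out <- summarize_wsi_tfi(ft), "excluding 1 field")
  expect_equal(out$mean_tfi[out$wsi_id == "w1"], mean(c(0.1, 0.2)))
  expect_equal(out$mean_tfi[out$wsi_id == "w2"], mean(c(0, 0.3)))
  expect_equal(out$n_fields[out$wsi_id == "w1"], 2)
})

test_that("risk groups follow the score cut-offs exactly", {
  g <- assign_groups(c(35, 10, 35, 18, 30, 31, 17.9), c(8, 5, 7, 6, 9, 8, 5))
  expect_equal(g$odx_risk,
               c("HIGH_ODX", "LOW_ODX", "HIGH_ODX", "INTERMEDIATE_ODX",
                 "INTERMEDIATE_ODX", "HIGH_ODX", "LOW_ODX"))
  expect_equal(g$hh_group, c("HH", "HHC", "HHC", "HHC", "HHC", "HH", "HHC"))
  expect_equal(g$ll_group, c("LLC", "LL", "LLC", "LLC", "LLC", "LLC", "LL"))
  # (35, 8) -> {HIGH, HH, LLC}; (10, 5) -> {LOW, HHC, LL};
  # (35, 7) stays HHC because BR > 7 is strict; (18, 6) is intermediate
  expect_error(assign_groups(-1, 5), "non-negative")
  expect_error(assign_groups(10, 2), "3..9")
})

test_that("group memberships partition every cohort", {
  set.seed(31)
  odx <- round(runif(200, 0, 60), 1)
  br <- sample(3:9, 200, replace = TRUE)
  g <- assign_groups(odx, br)
  expect_equal(sum(g$hh_group == "HH") + sum(g$hh_group == "HHC"), 200)
  expect_equal(sum(g$ll_group == "LL") + sum(g$ll_group == "LLC"), 200)
  expect_equal(sum(table(g$odx_risk)), 200)
})

test_that("welch t-test matches the closed form and stats::t.test", {
  w <- welch_ttest(c(1, 2, 3), c(4, 5, 6))
  # closed form: t = (2 - 5) / sqrt(1/3 + 1/3), df = 4
  expect_equal(w$t_statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(w$t_statistic, 3), -3.674)
  expect_equal(w$df, 4)

  a <- c(0.1, 0.4, 0.2, 0.5)
  same <- welch_ttest(a, a)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$mean_difference, 0)

  shifted <- welch_ttest(a + 10, c(0.2, 0.3, 0.9) + 10)
  orig <- welch_ttest(a, c(0.2, 0.3, 0.9))
  expect_equal(shifted$t_statistic, orig$t_statistic)
  expect_equal(shifted$df, orig$df)
  expect_equal(shifted$p_value, orig$p_value)

  expect_error(welch_ttest(1, c(2, 3)),
               class = "tubulequant_undersized_group")
})

test_that("welch t-test agrees with an independent implementation", {
  # closed-form Welch formulas evaluated directly
  welch_ref <- function(a, b) {
    va <- var(a) / length(a)
    vb <- var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    p <- 2 * stats::pt(-abs(t), df)
    c(t = t, df = df, p = p)
  }
  set.seed(12)
  for (i in 1:100) {
    a <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    got <- welch_ttest(a, b)
    ref <- welch_ref(a, b)
    expect_equal(got$t_statistic, unname(ref["t"]), tolerance = 1e-8)
    expect_equal(got$df, unname(ref["df"]), tolerance = 1e-8)
    expect_equal(got$p_value, unname(ref["p"]), tolerance = 1e-8)
  }
})

test_that("ROC analysis matches the pair-counting oracle", {
  perfect <- roc_from_tfi(c(0.3, 0.4), c(0.1, 0.2))
  expect_equal(perfect$auc, 1)
  expect_true(all(diff(perfect$points$fpr) >= 0))
  expect_true(all(diff(perfect$points$tpr) >= 0))
  expect_equal(perfect$points$fpr[1], 0)
  expect_equal(perfect$points$tpr[1], 0)
  expect_equal(utils::tail(perfect$points$fpr, 1), 1)
  expect_equal(utils::tail(perfect$points$tpr, 1), 1)

  same <- roc_from_tfi(c(0.2, 0.5), c(0.2, 0.5))
  expect_equal(same$auc, 0.5)

  worked <- roc_from_tfi(c(0.3, 0.2, 0.25), c(0.1, 0.22))
  expect_equal(worked$auc, 5 / 6, tolerance = 1e-12)

  set.seed(23)
  for (i in 1:60) {
    n_low <- sample(1:20, 1)
    n_high <- sample(1:20, 1)
    # quantised values force ties through the oracle's 0.5 weighting
    low <- sample(seq(0, 1, by = 0.1), n_low, replace = TRUE)
    high <- sample(seq(0, 1, by = 0.1), n_high, replace = TRUE)
    r <- roc_from_tfi(low, high)
    expect_equal(r$auc, auc_paircount(low, high), tolerance = 1e-12)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
  }
  expect_error(roc_from_tfi(numeric(0), 0.5), "non-empty")
})

test_that("ROC optimal threshold is the point closest to (0, 1)", {
  low <- c(0.30, 0.25, 0.20, 0.05)
  high <- c(0.02, 0.04, 0.10)
  r <- roc_from_tfi(low, high)
  pts <- r$points
  d <- sqrt(pts$fpr^2 + (1 - pts$tpr)^2)
  d_opt <- sqrt(r$optimal_point[["fpr"]]^2 + (1 - r$optimal_point[["tpr"]])^2)
  expect_equal(d_opt, min(d), tolerance = 1e-12)
  expect_equal(r$optimal_threshold, pts$threshold[which.min(d)])
})

test_that("the six comparisons run and flag undersized groups", {
  set.seed(44)
  wsi <- tibble::tibble(
    mean_tfi = c(runif(10, 0.0, 0.06), runif(10, 0.08, 0.2), runif(4, 0.02, 0.1)),
    odx_score = c(sample(31:50, 10, TRUE), sample(2:17, 10, TRUE),
                  sample(18:30, 4, TRUE)),
    br_grade = c(sample(8:9, 10, TRUE), sample(3:5, 10, TRUE),
                 sample(6:7, 4, TRUE)))
  cmp <- run_group_comparisons(wsi)
  expect_equal(nrow(cmp), 6)
  expect_true(all(cmp$ok))
  expect_equal(cmp$comparison,
               c("H vs L", "H vs L and I", "H and I vs L", "HH vs LL",
                 "LLc vs LL", "HH vs HHc"))
  hh_ll <- cmp[cmp$comparison == "HH vs LL", ]
  expect_equal(hh_ll$n_a + cmp$n_b[cmp$comparison == "HH vs HHc"], 24)
  # the generated effect (low risk has higher TFI) points the right way
  expect_lt(hh_ll$mean_difference, 0)
  expect_lt(hh_ll$p_value, 0.01)

  # drop the high group -> comparisons involving it are flagged, rest run
  low_only <- wsi[wsi$odx_score < 31, ]
  warns <- testthat::capture_warnings(
    cmp2 <- run_group_comparisons(low_only))
  expect_true(all(grepl("undersized", warns)))
  expect_false(all(cmp2$ok))
  expect_true(cmp2$ok[cmp2$comparison == "LLc vs LL"])

  # a group compared against itself gives t = 0
  self <- welch_ttest(wsi$mean_tfi[1:10], wsi$mean_tfi[1:10])
  expect_equal(self$t_statistic, 0)
})

test_that("null cohorts rarely produce significant comparisons", {
  # all groups share one generating distribution: p-values behave as nulls
  set.seed(99)
  hits <- 0
  n_rep <- 10
  for (rep in seq_len(n_rep)) {
    wsi <- tibble::tibble(
      mean_tfi = runif(30, 0.02, 0.2),
      odx_score = c(sample(31:50, 10, TRUE), sample(2:17, 10, TRUE),
                    sample(18:30, 10, TRUE)),
      br_grade = c(sample(8:9, 10, TRUE), sample(3:5, 10, TRUE),
                   sample(6:7, 10, TRUE)))
    cmp <- run_group_comparisons(wsi)
    if (all(cmp$p_value > 0.01)) hits <- hits + 1
  }
  expect_gte(hits, 0.9 * n_rep)
})
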
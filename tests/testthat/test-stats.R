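test_that("RECIST categories dichotomise as defined", {
  expect_equal(
    classify_response(c("CR", "PR", "SD", "PD", NA)),
    c("responder", "responder", "non-responder", "non-responder", "unclassified")
  )
  expect_error(classify_response("XX"), "Unknown RECIST")
})

test_that("worked Mann-Whitney examples hold exactly", {
  # complete separation at n = 3 vs 3: U = 0, exact two-sided P = 2/20
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6), test = "mann_whitney")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.100, tolerance = 1e-12)
  expect_equal(res$test_used, "mann_whitney")
  # complete separation at n = 5 vs 10: both extreme tails of C(15,5) splits
  a <- c(1.1, 2.2, 3.3, 4.4, 5.5)
  b <- a[c(1:5, 1:5)] + 100 + seq(0, 0.9, by = 0.1)
  res2 <- compare_groups(a, b, test = "mann_whitney")
  expect_equal(res2$p_value, 2 / 3003, tolerance = 1e-12)
})

test_that("identical groups are maximally non-significant under either test", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(compare_groups(x, x, test = "student_t")$p_value, 1)
  res <- compare_groups(x, x, test = "mann_whitney")
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, length(x)^2 / 2)  # U at its null mean
})

test_that("exact Mann-Whitney p-values match full enumeration (n <= 12)", {
  set.seed(55)
  sizes <- list(c(3, 3), c(3, 5), c(4, 4), c(4, 6), c(5, 5), c(5, 7), c(6, 6))
  for (sz in sizes) {
    a <- rnorm(sz[1])
    b <- rnorm(sz[2], mean = runif(1, -1, 1))
    got <- compare_groups(a, b, test = "mann_whitney")$p_value
    expect_equal(got, mw_exact_oracle(a, b), tolerance = 1e-12,
                 label = paste(sz, collapse = "v"))
  }
})

test_that("the normality gate picks Student's t only when both groups pass", {
  set.seed(8)
  norm_a <- rnorm(20)
  norm_b <- rnorm(20, 0.5)
  skew <- rexp(20)^3
  expect_equal(compare_groups(norm_a, norm_b)$test_used, "student_t")
  res <- compare_groups(norm_a, skew)
  expect_lt(res$shapiro_p_b, 0.05)
  expect_equal(res$test_used, "mann_whitney")
})

test_that("group comparison is invariant to the group labelling order", {
  set.seed(12)
  a <- rnorm(6)
  b <- rnorm(9, 1)
  ab <- compare_groups(a, b)
  ba <- compare_groups(b, a)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$mean_a, ba$mean_b)
  if (ab$test_used == "mann_whitney") {
    # the two U statistics are complements: U_ab + U_ba = n_a * n_b
    expect_equal(ab$statistic + ba$statistic, length(a) * length(b))
  }
  expect_error(compare_groups(c(1, 2), c(3, 4, 5)), "at least 3")
})

test_that("Spearman correlation reproduces hand-computed coefficients", {
  # d = (1, -1, 1, -1) on ranks: rho = 1 - 6*4 / (4 * 15)
  expect_equal(spearman_corr(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6, tolerance = 1e-12)
  x <- c(2, 5, 9, 13, 20)
  expect_equal(spearman_corr(x, exp(x / 10))$rho, 1)
  expect_equal(spearman_corr(x, -x)$rho, -1)
  expect_error(spearman_corr(x, rep(1, 5)), "constant")
  expect_error(spearman_corr(x, x[1:3]), "equal length")
})

test_that("Spearman rho equals the Pearson correlation of mid-ranks", {
  set.seed(33)
  for (i in 1:10) {
    x <- sample(1:8, 20, replace = TRUE)   # plenty of ties
    y <- x + sample(1:6, 20, replace = TRUE)
    expect_equal(
      spearman_corr(x, y)$rho,
      cor(rank(x), rank(y)),
      tolerance = 1e-12
    )
  }
})

test_that("ICC is 1 for duplicated ratings and penalises offsets only in agreement form", {
  base <- c(1.1, 2.3, 3.2, 4.8, 5.1, 6.9, 7.2, 8.4)
  dup <- cbind(base, base)
  perfect <- icc_agreement(dup)
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$ci_low, 1)
  # a large rater offset: consistency stays 1, agreement collapses
  off <- cbind(base, base + 10)
  expect_equal(icc_agreement(off, type = "consistency")$icc, 1, tolerance = 1e-12)
  agree <- icc_agreement(off, type = "agreement")
  expect_lt(agree$icc, 0.2)
  # any added offset strictly decreases the agreement form
  small_off <- icc_agreement(cbind(base, base + 1), type = "agreement")
  expect_lt(small_off$icc, 1)
  expect_gt(small_off$icc, agree$icc)
})

test_that("ICC confidence intervals bracket the estimate", {
  set.seed(77)
  m <- cbind(rnorm(10), rnorm(10)) + rnorm(10) * 2
  for (type in c("agreement", "consistency")) {
    res <- icc_agreement(m, type = type)
    expect_lte(res$ci_low, res$icc)
    expect_gte(res$ci_high, res$icc)
    expect_gte(res$icc, -1)
    expect_lte(res$icc, 1)
  }
  expect_error(icc_agreement(m[1:3, ]), "5 units")
  expect_error(icc_agreement(m[, 1, drop = FALSE]), "2 raters")
  m[2, 2] <- NA
  expect_error(icc_agreement(m), "complete")
})

test_that("agreement ICC matches the variance-component decomposition", {
  # independent route: ICC(A,1) as subject variance over total variance with
  # components recovered from the balanced two-way ANOVA expectations
  set.seed(21)
  n <- 12
  k <- 3
  subj <- rnorm(n, sd = 2)
  rater <- rnorm(k, sd = 0.7)
  m <- outer(subj, rep(1, k)) + outer(rep(1, n), rater) + rnorm(n * k, sd = 0.5)
  res <- icc_agreement(m, type = "agreement")
  msr <- k * var(rowMeans(m))
  msc <- n * var(colMeans(m))
  mse <- (sum((m - mean(m))^2) - (n - 1) * msr - (k - 1) * msc) / ((n - 1) * (k - 1))
  v_subj <- (msr - mse) / k
  v_rater <- (msc - mse) / n
  expect_equal(res$icc, v_subj / (v_subj + v_rater + mse), tolerance = 1e-12)
})

test_that("ICC of pure noise is centred on zero", {
  iccs <- vapply(1:300, function(s) {
    set.seed(s)
    icc_agreement(matrix(rnorm(12), 6, 2))$icc
  }, 1)
  expect_lt(abs(mean(iccs)), 0.08)
})

test_that("cohort analysis assembles comparisons and correlations as reported", {
  cohort <- simulate_cohort(seed = 101)
  hist_tb <- simulate_histology(cohort$k_app_voi, seed = 102)
  cohort <- dplyr::bind_cols(cohort, hist_tb)
  # two extra patients outside the response analysis, as in a cohort with
  # adjuvant-pathway cases
  extra <- cohort[1:2, ]
  extra$patient_id <- c("P90", "P91")
  extra$response_class <- "unclassified"
  cohort17 <- dplyr::bind_rows(cohort, extra)
  res <- run_cohort_analysis(cohort17)
  expect_s3_class(res$comparisons, "tbl_df")
  expect_equal(nrow(res$comparisons), 3)
  expect_equal(unique(res$comparisons$n_a), 5)
  expect_equal(unique(res$comparisons$n_b), 10)
  expect_equal(nrow(res$correlations), 6)
  expect_equal(unique(res$correlations$n), 17)
  # all-unclassified cohorts skip comparisons but keep correlations
  allu <- cohort
  allu$response_class <- "unclassified"
  res2 <- run_cohort_analysis(allu)
  expect_true(all(is.na(res2$comparisons$p_value)))
  expect_true(all(!is.na(res2$correlations$rho)))
})

test_that("cohort analysis tidies into one long hypothesis table", {
  cohort <- simulate_cohort(seed = 103)
  cohort <- dplyr::bind_cols(cohort,
                             simulate_histology(cohort$k_app_voi, seed = 104))
  res <- run_cohort_analysis(cohort)
  tb <- tidy(res)
  expect_equal(nrow(tb), 9)
  expect_setequal(unique(tb$analysis), c("group_comparison", "correlation"))
  gl <- glance(res)
  expect_equal(gl$n_patients, 15)
  expect_equal(gl$n_comparisons + gl$n_correlations, 9)
})

test_that("cohort reports are written as CSV plus JSON", {
  cohort <- simulate_cohort(seed = 105)
  res <- run_cohort_analysis(cohort)
  dir <- withr::local_tempdir()
  paths <- write_cohort_report(res, dir)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[["json"]])
  expect_equal(js$n_patients, 15)
  expect_length(js$comparisons, 3)
})
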
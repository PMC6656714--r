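#' Dichotomise RECIST categories into response classes
#'
#' Complete response (CR) and partial response (PR) map to `"responder"`;
#' stable disease (SD) and progressive disease (PD) to `"non-responder"`;
#' missing input to `"unclassified"` (e.g. patients managed outside the
#' neoadjuvant pathway, who enter correlations but not group comparisons).
#'
#' @param recist_category Character vector of RECIST categories
#'   (`CR`, `PR`, `SD`, `PD`) or `NA`.
#' @return Character vector of response classes.
#' @examples
#' classify_response(c("CR", "PR", "SD", "PD", NA))
#' @export
classify_response <- function(recist_category) {
  map <- c(CR = "responder", PR = "responder",
           SD = "non-responder", PD = "non-responder")
  out <- ifelse(is.na(recist_category) | recist_category == "",
                "unclassified",
                unname(map[toupper(as.character(recist_category))]))
  bad <- is.na(out)
  if (any(bad)) {
    abort(sprintf(
      "Unknown RECIST category: %s (expected CR, PR, SD, PD or NA).",
      paste(unique(recist_category[bad]), collapse = ", ")
    ))
  }
  out
}

#' Normality-gated two-group comparison
#'
#' The Shapiro-Wilk test is applied to each group at level `alpha`; if both
#' groups are consistent with normality, a two-sample Student's t-test (equal
#' variances) compares the groups, otherwise a two-sided Mann-Whitney U test.
#' The Mann-Whitney p-value uses the exact null distribution when both groups
#' are small and there are no ties, and the tie-corrected normal
#' approximation with continuity correction otherwise. Group means and SDs
#' are reported regardless of the test used.
#'
#' @param values_a,values_b Numeric vectors (each n >= 3).
#' @param alpha Level of the Shapiro-Wilk normality gate.
#' @param metric Optional metric name recorded in the result.
#' @param test `"auto"` (the gate decides), or force `"student_t"` /
#'   `"mann_whitney"`.
#' @return One-row tibble of class `group_comparison`: group sizes, means,
#'   SDs, Shapiro-Wilk p-values, `test_used`, `statistic` (t or U), and the
#'   two-sided `p_value`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6), test = "mann_whitney")
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05,
                           metric = NA_character_,
                           test = c("auto", "student_t", "mann_whitney")) {
  test <- match.arg(test)
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 3 || length(values_b) < 3) {
    abort("Each group needs at least 3 non-missing values.")
  }
  sw_p <- function(x) {
    # Shapiro-Wilk is undefined for a constant sample; a point mass is as
    # non-normal as it gets
    if (diff(range(x)) == 0) 0 else shapiro.test(x)$p.value
  }
  sh_a <- sw_p(values_a)
  sh_b <- sw_p(values_b)
  use_t <- switch(test,
    auto = sh_a > alpha && sh_b > alpha,
    student_t = TRUE,
    mann_whitney = FALSE
  )
  if (use_t) {
    ht <- t.test(values_a, values_b, var.equal = TRUE)
    test_used <- "student_t"
  } else {
    ht <- suppressWarnings(wilcox.test(values_a, values_b, correct = TRUE))
    test_used <- "mann_whitney"
  }
  structure(
    tibble(
      metric = metric,
      n_a = length(values_a), n_b = length(values_b),
      mean_a = mean(values_a), sd_a = sd(values_a),
      mean_b = mean(values_b), sd_b = sd(values_b),
      shapiro_p_a = sh_a, shapiro_p_b = sh_b,
      test_used = test_used,
      statistic = unname(ht$statistic),
      p_value = ht$p.value
    ),
    class = c("group_comparison", class(tibble()))
  )
}

#' Spearman rank correlation
#'
#' Mid-rank Spearman correlation with a two-sided p-value: the exact null
#' distribution for small untied samples (`exact = TRUE`, or automatically
#' when n <= 10 and there are no ties), otherwise the t-approximation on the
#' rank correlation.
#'
#' @param x,y Equal-length numeric vectors, n >= 3; neither may be constant.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact p-value;
#'   `NULL` decides automatically.
#' @param pair Optional character label of the variable pair.
#' @return One-row tibble of class `correlation_result`: `pair`, `n`, `rho`,
#'   `p_value`.
#' @examples
#' spearman_corr(c(1, 2, 3, 4), c(2, 1, 4, 3))
#' @export
spearman_corr <- function(x, y, exact = NULL, pair = NA_character_) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) abort("At least 3 complete pairs are required.")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    abort("Spearman's rho is undefined for a constant vector.")
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (is.null(exact)) exact <- n <= 10 && !ties
  rho <- cor(rank(x), rank(y))
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
  structure(
    tibble(pair = pair, n = n, rho = rho, p_value = ht$p.value),
    class = c("correlation_result", class(tibble()))
  )
}

#' Intraclass correlation coefficient for observer agreement
#'
#' Single-rater ICC from the two-way ANOVA decomposition of a complete
#' units-by-raters matrix. The default `"agreement"` form (two-way random
#' effects, absolute agreement, single rater) penalises systematic offsets
#' between raters; the `"consistency"` form does not. The 95% confidence
#' interval follows the F-distribution construction (Satterthwaite degrees of
#' freedom for the agreement form).
#'
#' @param ratings Numeric matrix, one row per measured unit, one column per
#'   rater; complete (no missing cells), >= 5 units, >= 2 raters.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @param conf_level Confidence level for the interval.
#' @param metric Optional metric label recorded in the result.
#' @return One-row tibble of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `model`, `n_units`, `n_raters`.
#' @examples
#' m <- cbind(r1 = c(1, 2, 3, 4, 5, 6), r2 = c(1.1, 2.0, 3.2, 3.9, 5.1, 6.0))
#' icc_agreement(m)
#' @export
icc_agreement <- function(ratings, type = c("agreement", "consistency"),
                          conf_level = 0.95, metric = NA_character_) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) abort("`ratings` must be complete (no missing cells).")
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 5) abort("At least 5 units are required.")
  if (k < 2) abort("At least 2 raters are required.")
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  grand <- mean(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level
  if (type == "consistency") {
    denom <- msr + (k - 1) * mse
    icc <- if (denom == 0) 1 else (msr - mse) / denom
    if (mse == 0) {
      lo <- hi <- icc
    } else {
      fobs <- msr / mse
      fl <- fobs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- fobs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      lo <- (fl - 1) / (fl + k - 1)
      hi <- (fu - 1) / (fu + k - 1)
    }
    model <- "two-way, consistency, single rater"
  } else {
    denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
    icc <- if (denom == 0) 1 else (msr - mse) / denom
    if (mse == 0 && msc == 0) {
      lo <- hi <- icc
    } else {
      # Satterthwaite approximation for the agreement-form interval
      a <- (k * icc) / (n * (1 - icc))
      b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f_up <- qf(1 - alpha / 2, n - 1, v)
      f_lo <- qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - f_up * mse) /
        (f_up * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (f_lo * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_lo * msr)
    }
    model <- "two-way, absolute agreement, single rater"
  }
  lo <- clip(lo, -1, min(icc, 1))
  hi <- clip(hi, max(icc, -1), 1)
  structure(
    tibble(
      metric = metric, icc = icc, ci_low = lo, ci_high = hi,
      model = model, n_units = n, n_raters = k
    ),
    class = c("icc_result", class(tibble()))
  )
}

#' Run the full cohort inference chain
#'
#' For each diffusion metric (K_app, D_app, ADC) compares responders with
#' non-responders via the normality-gated test of [compare_groups()], and
#' correlates each metric with the available histology covariates
#' (cellularity, Ki-67) via [spearman_corr()]. Patients with an unclassified
#' response are excluded from the comparisons but retained for the
#' correlations. Analyses with insufficient data are reported as `NA` rows,
#' not errors.
#'
#' @param cohort A cohort tibble (see [read_cohort_table()]) with VOI metric
#'   columns and optionally histology columns.
#' @param alpha Significance level used for the normality gate (and quoted in
#'   the report).
#' @return A `cohort_analysis` list: `comparisons` (one row per metric),
#'   `correlations` (one row per metric x covariate), `n_patients`, `alpha`.
#' @export
run_cohort_analysis <- function(cohort, alpha = 0.05) {
  cohort <- validate_cohort_table(cohort)
  metrics <- intersect(c("k_app_voi", "d_app_voi", "adc_voi"), names(cohort))
  if (length(metrics) == 0) abort("Cohort has no VOI metric columns.")
  resp <- cohort[cohort$response_class == "responder", , drop = FALSE]
  nonr <- cohort[cohort$response_class == "non-responder", , drop = FALSE]
  comparisons <- purrr::map_dfr(metrics, function(m) {
    a <- resp[[m]][!is.na(resp[[m]])]
    b <- nonr[[m]][!is.na(nonr[[m]])]
    if (length(a) < 3 || length(b) < 3) {
      return(tibble(
        metric = m, n_a = length(a), n_b = length(b),
        mean_a = NA_real_, sd_a = NA_real_, mean_b = NA_real_, sd_b = NA_real_,
        shapiro_p_a = NA_real_, shapiro_p_b = NA_real_,
        test_used = NA_character_, statistic = NA_real_, p_value = NA_real_
      ))
    }
    compare_groups(a, b, alpha = alpha, metric = m)
  })
  covariates <- intersect(c("cellularity_cells_per_um2", "ki67_percent"),
                          names(cohort))
  correlations <- purrr::map_dfr(metrics, function(m) {
    purrr::map_dfr(covariates, function(cv) {
      keep <- !is.na(cohort[[m]]) & !is.na(cohort[[cv]])
      label <- paste(m, cv, sep = " ~ ")
      if (sum(keep) < 3) {
        return(tibble(pair = label, n = sum(keep),
                      rho = NA_real_, p_value = NA_real_))
      }
      spearman_corr(cohort[[m]][keep], cohort[[cv]][keep], pair = label)
    })
  })
  structure(
    list(
      comparisons = as_tibble(comparisons),
      correlations = as_tibble(correlations),
      n_patients = nrow(cohort),
      alpha = alpha
    ),
    class = "cohort_analysis"
  )
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d patients, alpha = %g\n", x$n_patients, x$alpha))
  cat("\nGroup comparisons (responder vs non-responder):\n")
  print(x$comparisons)
  if (nrow(x$correlations) > 0) {
    cat("\nHistology correlations (Spearman):\n")
    print(x$correlations)
  }
  invisible(x)
}

#' Write a cohort analysis report to CSV and JSON
#'
#' Writes `comparisons.csv`, `correlations.csv` and a combined
#' machine-readable `report.json` into `out_dir`.
#'
#' @param analysis A `cohort_analysis` from [run_cohort_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the paths written.
#' @export
write_cohort_report <- function(analysis, out_dir) {
  stopifnot(inherits(analysis, "cohort_analysis"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(
    comparisons = file.path(out_dir, "comparisons.csv"),
    correlations = file.path(out_dir, "correlations.csv"),
    json = file.path(out_dir, "report.json")
  )
  readr::write_csv(analysis$comparisons, paths[["comparisons"]], progress = FALSE)
  readr::write_csv(analysis$correlations, paths[["correlations"]], progress = FALSE)
  jsonlite::write_json(
    list(
      n_patients = analysis$n_patients,
      alpha = analysis$alpha,
      comparisons = analysis$comparisons,
      correlations = analysis$correlations
    ),
    paths[["json"]],
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  paths
}
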
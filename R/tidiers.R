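#' Tidy voxel-wise parameter maps into a long tibble
#'
#' One row per fitted voxel (`qc == 0` unless `all_voxels = TRUE`) with voxel
#' indices and the four metrics.
#'
#' @param x A [parameter_maps()] object.
#' @param all_voxels Include unfitted voxels (with `NaN` metrics)?
#' @param ... Unused.
#' @return A tibble with columns `i`, `j`, `k`, `s0`, `d_app`, `k_app`,
#'   `adc`, `qc`.
#' @export
tidy.parameter_maps <- function(x, all_voxels = FALSE, ...) {
  idx <- if (all_voxels) seq_along(x$qc) else which(x$qc == 0L)
  co <- arrayInd(idx, dim(x$qc))
  tibble(
    i = co[, 1], j = co[, 2], k = co[, 3],
    s0 = x$s0[idx], d_app = x$d_app[idx], k_app = x$k_app[idx],
    adc = x$adc[idx], qc = x$qc[idx]
  )
}

#' One-row fit-quality summary of parameter maps
#'
#' @param x A [parameter_maps()] object.
#' @param ... Unused.
#' @return Tibble with voxel counts per qc status and the convergence rate
#'   over attempted voxels.
#' @export
glance.parameter_maps <- function(x, ...) {
  attempted <- sum(x$qc != 1L)
  tibble(
    n_voxels = length(x$qc),
    n_fitted = sum(x$qc == 0L),
    n_nonpositive = sum(x$qc == 2L),
    n_nonconverged = sum(x$qc == 3L),
    convergence_rate = if (attempted == 0) NA_real_ else sum(x$qc == 0L) / attempted
  )
}

#' Tidy a cohort analysis into one long table
#'
#' Stacks the group comparisons and histology correlations into one tibble
#' with an `analysis` discriminator column, one row per hypothesis test.
#'
#' @param x A `cohort_analysis` from [run_cohort_analysis()].
#' @param ... Unused.
#' @return A tibble with columns `analysis`, `term`, `estimate`,
#'   `statistic`, `p_value`, `method`, `n`.
#' @export
tidy.cohort_analysis <- function(x, ...) {
  cmp <- dplyr::transmute(
    x$comparisons,
    analysis = "group_comparison",
    term = .data$metric,
    estimate = .data$mean_a - .data$mean_b,
    statistic = .data$statistic,
    p_value = .data$p_value,
    method = .data$test_used,
    n = .data$n_a + .data$n_b
  )
  cor <- dplyr::transmute(
    x$correlations,
    analysis = "correlation",
    term = .data$pair,
    estimate = .data$rho,
    statistic = NA_real_,
    p_value = .data$p_value,
    method = "spearman",
    n = .data$n
  )
  dplyr::bind_rows(cmp, cor)
}

#' One-row summary of a cohort analysis
#'
#' @param x A `cohort_analysis`.
#' @param ... Unused.
#' @return Tibble with patient counts and the number of significant tests at
#'   the analysis alpha.
#' @export
glance.cohort_analysis <- function(x, ...) {
  tb <- tidy(x)
  tibble(
    n_patients = x$n_patients,
    n_comparisons = nrow(x$comparisons),
    n_correlations = nrow(x$correlations),
    n_significant = sum(tb$p_value < x$alpha, na.rm = TRUE),
    alpha = x$alpha
  )
}
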
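#' Plot an axial slice of each parameter map
#'
#' Facetted heatmap of S0, D_app, K_app and ADC at one axial slice;
#' diffusivities are shown scaled by 1000 (mm^2/s x 1000), the conventional
#' display scaling.
#'
#' @param object A [parameter_maps()] object.
#' @param slice Axial slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.parameter_maps <- function(object, slice = NULL, ...) {
  dims <- dim(object$qc)
  if (is.null(slice)) slice <- ceiling(dims[3] / 2)
  tb <- tidy(object, all_voxels = TRUE)
  tb <- dplyr::filter(tb, .data$k == slice)
  tb <- dplyr::mutate(
    tb,
    d_app = .data$d_app * 1000, adc = .data$adc * 1000
  )
  long <- tidyr::pivot_longer(
    tb, c("s0", "d_app", "k_app", "adc"),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(
    long$metric,
    levels = c("s0", "d_app", "k_app", "adc"),
    labels = c("S0", "D_app (x1000)", "K_app", "ADC (x1000)")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$i, .data$j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("Parameter maps, axial slice %d", slice),
      x = NULL, y = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Boxplots of VOI metrics by response group
#'
#' Median/IQR boxplots of per-patient K_app, D_app and ADC for responders and
#' non-responders, with individual patients overplotted.
#'
#' @param cohort A cohort tibble with `response_class` and VOI metric columns.
#' @return A ggplot object.
#' @export
plot_group_metrics <- function(cohort) {
  cohort <- validate_cohort_table(cohort)
  metrics <- intersect(c("k_app_voi", "d_app_voi", "adc_voi"), names(cohort))
  long <- tidyr::pivot_longer(
    cohort[c("response_class", metrics)],
    dplyr::all_of(metrics),
    names_to = "metric", values_to = "value"
  )
  long <- dplyr::filter(long, .data$response_class != "unclassified")
  ggplot2::ggplot(long, ggplot2::aes(.data$response_class, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatterplot of a diffusion metric against a histology covariate
#'
#' @param cohort A cohort tibble.
#' @param metric VOI metric column name (e.g. `"k_app_voi"`).
#' @param covariate Histology column name (e.g. `"ki67_percent"`).
#' @return A ggplot object annotated with the Spearman rho and p-value.
#' @export
plot_histology_correlation <- function(cohort, metric = "k_app_voi",
                                       covariate = "ki67_percent") {
  cohort <- validate_cohort_table(cohort)
  if (!metric %in% names(cohort) || !covariate %in% names(cohort)) {
    abort("`metric` and `covariate` must be cohort columns.")
  }
  res <- spearman_corr(cohort[[metric]], cohort[[covariate]])
  ggplot2::ggplot(cohort, ggplot2::aes(.data[[metric]], .data[[covariate]])) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$response_class), size = 2.5) +
    ggplot2::labs(
      subtitle = sprintf("Spearman rho = %.2f, P = %.3g", res$rho, res$p_value),
      shape = NULL
    ) +
    ggplot2::theme_minimal()
}
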
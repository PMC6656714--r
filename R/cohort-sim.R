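#' Per-group distribution of VOI-level metrics
#'
#' Describes one response group for [simulate_cohort()]: the number of
#' patients and the per-patient (VOI-level) normal distributions of K_app,
#' D_app and ADC. Defaults for the two groups are provided by
#' [responder_group_spec()] and [non_responder_group_spec()], which carry the
#' study conditions this package is validated against: responders
#' K_app 0.69 +/- 0.13, D_app 1.44 +/- 0.30 e-3 mm^2/s, ADC 1.22 +/- 0.24 e-3;
#' non-responders K_app 0.51 +/- 0.11, D_app 1.51 +/- 0.32 e-3,
#' ADC 1.30 +/- 0.27 e-3.
#'
#' @param n_patients Number of patients (>= 1).
#' @param k_app_mean,k_app_sd K_app distribution (unitless; mean >= 0, sd >= 0).
#' @param d_app_mean,d_app_sd D_app distribution (mm^2/s).
#' @param adc_mean,adc_sd ADC distribution (mm^2/s).
#' @return A `group_spec` list.
#' @export
group_spec <- function(n_patients, k_app_mean, k_app_sd,
                       d_app_mean, d_app_sd, adc_mean, adc_sd) {
  if (n_patients < 1) abort("`n_patients` must be >= 1.")
  sds <- c(k_app_sd, d_app_sd, adc_sd)
  if (any(sds < 0)) abort("Standard deviations must be >= 0.")
  if (k_app_mean < 0 || d_app_mean <= 0 || adc_mean <= 0) {
    abort("Means must be positive (K_app mean >= 0).")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      k_app_mean = k_app_mean, k_app_sd = k_app_sd,
      d_app_mean = d_app_mean, d_app_sd = d_app_sd,
      adc_mean = adc_mean, adc_sd = adc_sd
    ),
    class = "group_spec"
  )
}

#' @rdname group_spec
#' @export
responder_group_spec <- function(n_patients = 5) {
  group_spec(n_patients,
             k_app_mean = 0.69, k_app_sd = 0.13,
             d_app_mean = 1.44e-3, d_app_sd = 0.30e-3,
             adc_mean = 1.22e-3, adc_sd = 0.24e-3)
}

#' @rdname group_spec
#' @export
non_responder_group_spec <- function(n_patients = 10) {
  group_spec(n_patients,
             k_app_mean = 0.51, k_app_sd = 0.11,
             d_app_mean = 1.51e-3, d_app_sd = 0.32e-3,
             adc_mean = 1.30e-3, adc_sd = 0.27e-3)
}

#' Simulate a two-group patient cohort
#'
#' Draws per-patient VOI-level K_app, D_app and ADC from each group's normal
#' distributions (K_app truncated at 0, diffusivities at 1e-5 mm^2/s) and
#' labels patients responder / non-responder. The generating draws are also
#' stored in `*_true` columns so recovery through a downstream pipeline can
#' be checked against them.
#'
#' @param responders,non_responders [group_spec()] objects.
#' @param seed Integer seed; the cohort is a pure function of its arguments.
#' @return A cohort tibble with columns `patient_id`, `response_class`,
#'   `k_app_voi`, `d_app_voi`, `adc_voi` and matching `*_true` columns.
#' @examples
#' simulate_cohort(seed = 1)
#' @export
simulate_cohort <- function(responders = responder_group_spec(),
                            non_responders = non_responder_group_spec(),
                            seed) {
  stopifnot(inherits(responders, "group_spec"),
            inherits(non_responders, "group_spec"))
  withr::with_seed(seed, {
    draw_group <- function(spec, class, id_offset) {
      n <- spec$n_patients
      tibble(
        patient_id = sprintf("P%02d", id_offset + seq_len(n)),
        response_class = class,
        k_app_voi = rtruncnorm(n, spec$k_app_mean, spec$k_app_sd, lower = 0),
        d_app_voi = rtruncnorm(n, spec$d_app_mean, spec$d_app_sd, lower = 1e-5),
        adc_voi = rtruncnorm(n, spec$adc_mean, spec$adc_sd, lower = 1e-5)
      )
    }
    out <- dplyr::bind_rows(
      draw_group(responders, "responder", 0L),
      draw_group(non_responders, "non-responder", responders$n_patients)
    )
    out$k_app_true <- out$k_app_voi
    out$d_app_true <- out$d_app_voi
    out$adc_true <- out$adc_voi
    validate_cohort_table(out)
  })
}

# Expected sample Spearman rho between fixed scores z1 and
# z2 = r * z1 + sqrt(1 - r^2) * e, e ~ N(0, 1). Rank vectors are
# permutations, so sum(R2^2) is constant and the expectation is linear in
# E[R2_i] = 1 + sum_j P(z2_j < z2_i), each term a Gaussian orthant
# probability. Exact for distinct z1 (no ties).
expected_spearman_fixed <- function(r, z1) {
  if (abs(r) >= 1) return(sign(r))
  n <- length(z1)
  P <- pnorm(outer(z1, z1, "-") * r / sqrt(2 * (1 - r^2)))
  diag(P) <- 0
  er2 <- 1 + rowSums(P)
  r1 <- rank(z1)
  (sum(r1 * er2) - n * (n + 1)^2 / 4) / (n * (n^2 - 1) / 12)
}

# invert the expected-Spearman map to find the latent Gaussian coefficient
calibrate_copula_r <- function(rho_target, z1) {
  if (abs(rho_target) >= 1) return(sign(rho_target))
  if (rho_target == 0) return(0)
  uniroot(
    function(r) expected_spearman_fixed(r, z1) - rho_target,
    interval = c(-1 + 1e-9, 1 - 1e-9), tol = 1e-10
  )$root
}

#' Simulate histology covariates rank-correlated with kurtosis
#'
#' Generates tumour cellularity (cells/um^2) and Ki-67 positive-cell
#' percentage vectors whose expected sample Spearman correlation with the
#' supplied K_app values matches `rho_target`. The construction is a Gaussian
#' copula: K_app is rank-transformed to normal scores `z1`, a latent
#' `z2 = r z1 + sqrt(1 - r^2) e` is drawn, and `pnorm(z2)` is pushed through
#' the covariate's marginal quantile function (log-normal for cellularity,
#' scaled Beta for Ki-67). The latent coefficient `r` is calibrated by
#' inverting the exact finite-sample expectation of Spearman's rho for fixed
#' normal scores, a sharper version of the classical large-sample
#' `r = 2 sin(pi * rho / 6)` correction.
#'
#' @param k_app_values Numeric vector of per-patient K_app (length >= 3).
#' @param rho_target Target Spearman correlation(s) in `[-1, 1]`: a single
#'   value for both covariates, or length 2 (cellularity, Ki-67). Defaults to
#'   the study conditions 0.49 (cellularity) and 0.53 (Ki-67).
#' @param seed Integer seed.
#' @return Tibble with columns `cellularity_cells_per_um2` (> 0) and
#'   `ki67_percent` (in `[0, 100]`).
#' @export
simulate_histology <- function(k_app_values, rho_target = c(0.49, 0.53), seed) {
  n <- length(k_app_values)
  if (n < 3) abort("At least 3 K_app values are required.")
  if (any(abs(rho_target) > 1)) abort("`rho_target` must lie in [-1, 1].")
  if (!length(rho_target) %in% c(1, 2)) {
    abort("`rho_target` must have length 1 or 2 (cellularity, Ki-67).")
  }
  if (length(rho_target) == 1) rho_target <- rep(rho_target, 2)
  withr::with_seed(seed, {
    z1 <- qnorm((rank(k_app_values, ties.method = "average") - 0.5) / n)
    draw_latent <- function(rho) {
      r <- calibrate_copula_r(rho, z1)
      if (abs(r) == 1) return(sign(r) * z1)
      r * z1 + sqrt(1 - r^2) * rnorm(n)
    }
    u_cell <- pnorm(draw_latent(rho_target[1]))
    u_ki67 <- pnorm(draw_latent(rho_target[2]))
    tibble(
      # marginals: HGSOC-like cellularity around 5e-3 cells/um^2 and a broad
      # Ki-67 distribution centred near 45%
      cellularity_cells_per_um2 = qlnorm(u_cell, meanlog = log(5e-3), sdlog = 0.35),
      ki67_percent = 100 * qbeta(u_ki67, shape1 = 2.5, shape2 = 3)
    )
  })
}
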
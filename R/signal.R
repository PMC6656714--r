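#' Diffusion kurtosis signal model
#'
#' Signal intensity of the (isotropic, trace-weighted) diffusion kurtosis
#' model:
#' \deqn{S(b) = S_0 \exp(-b D_{app} + \tfrac{1}{6} b^2 D_{app}^2 K_{app})}
#' where `d_app` is the apparent diffusivity in mm^2/s and `k_app` the
#' unitless apparent kurtosis. At `k_app = 0` the model reduces to
#' mono-exponential (Gaussian) decay.
#'
#' @param b Numeric vector of b-values in s/mm^2 (>= 0).
#' @param s0 Signal at b = 0 (extrapolated; > 0).
#' @param d_app Apparent diffusivity, mm^2/s (> 0).
#' @param k_app Apparent kurtosis, unitless (>= 0).
#' @return Numeric vector of signals, same length as `b`.
#' @examples
#' dki_signal(c(100, 500, 900, 1300, 1700), s0 = 1000, d_app = 1.44e-3, k_app = 0.69)
#' @export
dki_signal <- function(b, s0, d_app, k_app) {
  b <- as.numeric(b)
  if (any(b < 0)) abort("`b` must be non-negative.")
  if (s0 <= 0) abort("`s0` must be positive.")
  if (d_app <= 0) abort("`d_app` must be positive.")
  if (k_app < 0) abort("`k_app` must be non-negative.")
  s0 * exp(-b * d_app + (b^2 * d_app^2 * k_app) / 6)
}

#' Mono-exponential (Gaussian) diffusion signal model
#'
#' Conventional apparent-diffusion-coefficient decay
#' \eqn{S(b) = S_0 \exp(-b \cdot ADC)}. Identical to [dki_signal()] with
#' `k_app = 0`.
#'
#' @inheritParams dki_signal
#' @param adc Apparent diffusion coefficient, mm^2/s (> 0).
#' @return Numeric vector of signals.
#' @export
adc_signal <- function(b, s0, adc) {
  b <- as.numeric(b)
  if (any(b < 0)) abort("`b` must be non-negative.")
  if (s0 <= 0) abort("`s0` must be positive.")
  if (adc <= 0) abort("`adc` must be positive.")
  s0 * exp(-b * adc)
}
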
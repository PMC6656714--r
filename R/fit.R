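#' Options controlling the voxel-wise fits
#'
#' Bounds, convergence control and the ADC b-value subset used by
#' [fit_dki_voxel()], [fit_adc_voxel()] and [fit_volume()].
#'
#' Defaults: diffusivity is constrained to the physiological range
#' 1e-5 to 4e-3 mm^2/s, kurtosis to 0 to 3, and S0 to (0, 2 * max(signal)]
#' (the S0 ceiling is resolved per voxel when `s0_max = NULL`). The ADC is
#' fitted on the b = 100, 500, 900 s/mm^2 subset by log-linear least squares.
#' An optional `noise_floor` offset can be added to the kurtosis model to
#' absorb the Rician noise floor at high b; it is 0 (off) by default.
#'
#' @param d_bounds Length-2, lower/upper bound on D_app in mm^2/s.
#' @param k_bounds Length-2, lower/upper bound on K_app (unitless).
#' @param s0_max Upper bound for S0, or `NULL` to use 2 * max(signal) per voxel.
#' @param adc_bvalues b-values (s/mm^2) used for the mono-exponential ADC fit.
#' @param max_iter Maximum solver iterations.
#' @param tol Relative tolerance on parameters and cost.
#' @param noise_floor Constant offset added to the model signal (off = 0).
#' @return A `fit_options` list.
#' @export
fit_options <- function(d_bounds = c(1e-5, 4e-3),
                        k_bounds = c(0, 3),
                        s0_max = NULL,
                        adc_bvalues = c(100, 500, 900),
                        max_iter = 500L,
                        tol = 1e-8,
                        noise_floor = 0) {
  if (length(d_bounds) != 2 || diff(d_bounds) <= 0 || d_bounds[1] <= 0) {
    abort("`d_bounds` must be ordered positive bounds.")
  }
  if (length(k_bounds) != 2 || diff(k_bounds) < 0 || k_bounds[1] < 0) {
    abort("`k_bounds` must be ordered with a non-negative lower bound.")
  }
  if (length(adc_bvalues) < 2) {
    abort("`adc_bvalues` needs at least 2 b-values.")
  }
  if (noise_floor < 0) abort("`noise_floor` must be non-negative.")
  structure(
    list(
      d_bounds = as.numeric(d_bounds), k_bounds = as.numeric(k_bounds),
      s0_max = s0_max, adc_bvalues = sort(as.numeric(adc_bvalues)),
      max_iter = as.integer(max_iter), tol = tol, noise_floor = noise_floor
    ),
    class = "fit_options"
  )
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Log-quadratic initial estimate for the kurtosis fit
#'
#' Ordinary least squares of log signal on (1, -b, b^2) gives starting values
#' for (S0, D_app, K_app). The regression is exact for noiseless kurtosis
#' signals, so the nonlinear solver then starts at (or at the bound-clipped
#' projection of) the true optimum. Degenerate designs fall back to
#' (median signal, 1e-3 mm^2/s, 0.5).
#'
#' @param signal Positive signal vector, one value per b.
#' @param scheme A [bvalue_scheme()] (or numeric b-vector).
#' @param options A [fit_options()] used to clip the estimate into bounds.
#' @return Named numeric vector `c(s0, d_app, k_app)`.
#' @export
initial_estimate <- function(signal, scheme, options = fit_options()) {
  scheme <- as_bvalue_scheme(scheme)
  if (length(signal) != length(scheme)) abort("signal/scheme length mismatch.")
  if (any(signal <= 0)) abort("All signals must be positive for the log-domain start.")
  b <- as.numeric(scheme)
  fallback <- c(s0 = median(signal), d_app = 1e-3, k_app = 0.5)
  est <- tryCatch({
    co <- coef(lm(log(signal) ~ b + I(b^2)))
    s0 <- exp(co[[1]])
    d <- -co[[2]]
    k <- if (d > 0) 6 * co[[3]] / d^2 else NA_real_
    c(s0 = s0, d_app = d, k_app = k)
  }, error = function(e) fallback)
  if (anyNA(est) || any(!is.finite(est))) est <- fallback
  s0_hi <- if (is.null(options$s0_max)) 2 * max(signal) else options$s0_max
  c(
    s0 = clip(est[["s0"]], .Machine$double.eps, s0_hi),
    d_app = clip(est[["d_app"]], options$d_bounds[1], options$d_bounds[2]),
    k_app = clip(est[["k_app"]], options$k_bounds[1], options$k_bounds[2])
  )
}

new_voxel_fit <- function(s0, d_app, k_app, adc, converged, rss, n_iter = NA_integer_) {
  tibble(
    s0 = s0, d_app = d_app, k_app = k_app, adc = adc,
    converged = converged, rss = rss, n_iter = as.integer(n_iter)
  )
}

#' Fit the kurtosis model to a single voxel
#'
#' Bound-constrained nonlinear least squares of the raw (untransformed) signal
#' against [dki_signal()], initialised by [initial_estimate()]. The objective
#' is the unweighted residual sum of squares; fitting on the raw signal avoids
#' the log transform amplifying noise at high b.
#'
#' @param signal Signal vector, one value per scheme b-value; at least 3
#'   positive samples.
#' @param scheme A [bvalue_scheme()].
#' @param options A [fit_options()].
#' @return One-row tibble with `s0`, `d_app`, `k_app`, `adc` (`NA`, not fitted
#'   here; see [fit_adc_voxel()]), `converged`, `rss`, `n_iter`. Non-converged
#'   fits carry `NaN` parameters and `converged = FALSE`.
#' @examples
#' b <- bvalue_scheme(c(100, 500, 900, 1300, 1700))
#' s <- dki_signal(b, 1000, 1.44e-3, 0.69)
#' fit_dki_voxel(s, b)
#' @export
fit_dki_voxel <- function(signal, scheme, options = fit_options()) {
  scheme <- as_bvalue_scheme(scheme)
  if (length(signal) != length(scheme)) abort("signal/scheme length mismatch.")
  if (all(signal == 0)) abort("All-zero signal cannot be fitted.")
  if (sum(signal > 0) < 3) abort("At least 3 positive samples are required.")
  if (any(signal <= 0)) {
    # log-domain start is undefined; treat as unfittable rather than guessing
    return(new_voxel_fit(NaN, NaN, NaN, NA_real_, FALSE, NaN))
  }
  b <- as.numeric(scheme)
  start <- initial_estimate(signal, scheme, options)
  s0_hi <- if (is.null(options$s0_max)) 2 * max(signal) else options$s0_max
  lower <- c(.Machine$double.eps, options$d_bounds[1], options$k_bounds[1])
  upper <- c(s0_hi, options$d_bounds[2], options$k_bounds[2])
  offset <- options$noise_floor
  resid_fn <- function(p) {
    signal - (p[1] * exp(-b * p[2] + (b^2 * p[2]^2 * p[3]) / 6) + offset)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = pmin(pmax(start, lower), upper),
      lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = min(options$max_iter, 1024L),
        ftol = options$tol, ptol = options$tol
      )
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !(fit$info %in% 1:4)) {
    return(new_voxel_fit(NaN, NaN, NaN, NA_real_, FALSE, NaN,
                         if (is.null(fit)) NA_integer_ else fit$niter))
  }
  p <- fit$par
  new_voxel_fit(p[[1]], p[[2]], p[[3]], NA_real_, TRUE, sum(resid_fn(p)^2), fit$niter)
}

#' Fit the mono-exponential ADC on a b-value subset
#'
#' Ordinary least squares of log signal on -b over the chosen subset of the
#' scheme (log-linear fit). With two b-values this is the exact two-point
#' slope.
#'
#' @inheritParams fit_dki_voxel
#' @param subset b-values (s/mm^2) to use; must all be present in the scheme.
#' @return The fitted ADC in mm^2/s (a single number).
#' @examples
#' b <- bvalue_scheme(c(100, 500, 900, 1300, 1700))
#' s <- adc_signal(b, 1000, 1.22e-3)
#' fit_adc_voxel(s, b)
#' @export
fit_adc_voxel <- function(signal, scheme, subset = c(100, 500, 900)) {
  scheme <- as_bvalue_scheme(scheme)
  if (length(signal) != length(scheme)) abort("signal/scheme length mismatch.")
  idx <- match(subset, as.numeric(scheme))
  if (anyNA(idx)) {
    abort("`subset` must be a subset of the scheme's b-values.")
  }
  if (length(idx) < 2) abort("ADC needs at least 2 b-values.")
  s <- signal[idx]
  if (any(s <= 0)) abort("Signals in the ADC subset must be positive.")
  b <- as.numeric(scheme)[idx]
  co <- coef(lm(log(s) ~ b))
  -co[[2]]
}

#' Fit every masked voxel of a DWI series
#'
#' Runs the kurtosis fit ([fit_dki_voxel()]) and the mono-exponential ADC fit
#' ([fit_adc_voxel()]) at every voxel with a positive mask label and assembles
#' [parameter_maps()]. Voxels with any non-positive signal get qc = 2; voxels
#' whose kurtosis fit fails to converge get qc = 3; unmasked voxels get qc = 1.
#' Fitting is deterministic: repeated calls give identical maps.
#'
#' @param series A [dwi_series()].
#' @param mask An [roi_mask()] on the same grid.
#' @param options A [fit_options()].
#' @return A [parameter_maps()] object.
#' @export
fit_volume <- function(series, mask, options = fit_options()) {
  stopifnot(inherits(series, "dwi_series"))
  mask <- if (inherits(mask, "roi_mask")) mask else roi_mask(mask)
  grid <- dim(series$signal)[1:3]
  if (!identical(dim(mask$labels), grid)) {
    abort("Mask grid does not match the series grid.")
  }
  idx <- which(mask$labels > 0L)
  nan_map <- array(NaN, grid)
  qc <- array(1L, grid)
  s0 <- d_app <- k_app <- adc <- nan_map
  if (length(idx) == 0) {
    warn("Empty mask: returning all-NaN parameter maps.")
    return(parameter_maps(s0, d_app, k_app, adc, qc, series$voxel_size))
  }
  nb <- length(series$scheme)
  sig_mat <- matrix(aperm(series$signal, c(4, 1, 2, 3)), nrow = nb)[, idx, drop = FALSE]
  for (j in seq_along(idx)) {
    v <- idx[j]
    s <- sig_mat[, j]
    if (any(s <= 0)) {
      qc[v] <- 2L
      next
    }
    fit <- fit_dki_voxel(s, series$scheme, options)
    if (!fit$converged) {
      qc[v] <- 3L
      next
    }
    s0[v] <- fit$s0
    d_app[v] <- fit$d_app
    k_app[v] <- fit$k_app
    adc[v] <- fit_adc_voxel(s, series$scheme, options$adc_bvalues)
    qc[v] <- 0L
  }
  parameter_maps(s0, d_app, k_app, adc, qc, series$voxel_size)
}

#' Exhaustive grid-search fit (test oracle)
#'
#' Evaluates the residual sum of squares of the kurtosis model over every
#' point of a finite (s0, d_app, k_app) grid and returns the arg-min. This is
#' a brute-force reference used in tests to bound the nonlinear solver (the
#' solver's rss must never exceed the best grid point's); it is far too slow
#' for real use.
#'
#' @inheritParams fit_dki_voxel
#' @param grid_spec Named list with numeric vectors `s0`, `d_app`, `k_app`.
#' @return One-row tibble like [fit_dki_voxel()]'s (with `converged = TRUE`).
#' @export
grid_oracle_fit <- function(signal, scheme, grid_spec) {
  scheme <- as_bvalue_scheme(scheme)
  if (length(signal) != length(scheme)) abort("signal/scheme length mismatch.")
  if (!all(c("s0", "d_app", "k_app") %in% names(grid_spec)) ||
      any(lengths(grid_spec[c("s0", "d_app", "k_app")]) == 0)) {
    abort("`grid_spec` must contain non-empty vectors s0, d_app, k_app.")
  }
  b <- as.numeric(scheme)
  grid <- expand.grid(
    s0 = grid_spec$s0, d_app = grid_spec$d_app, k_app = grid_spec$k_app,
    KEEP.OUT.ATTRS = FALSE
  )
  # decay profile depends only on (d, k); evaluate those once per pair
  dk <- unique(grid[c("d_app", "k_app")])
  decay <- vapply(
    seq_len(nrow(dk)),
    function(i) exp(-b * dk$d_app[i] + (b^2 * dk$d_app[i]^2 * dk$k_app[i]) / 6),
    numeric(length(b))
  )
  best <- list(rss = Inf, par = NULL)
  for (i in seq_len(nrow(dk))) {
    for (s0 in grid_spec$s0) {
      rss <- sum((signal - s0 * decay[, i])^2)
      if (rss < best$rss) {
        best <- list(rss = rss, par = c(s0, dk$d_app[i], dk$k_app[i]))
      }
    }
  }
  new_voxel_fit(best$par[1], best$par[2], best$par[3], NA_real_, TRUE, best$rss)
}
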
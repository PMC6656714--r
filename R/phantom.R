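#' Specification of one ellipsoidal phantom lesion
#'
#' Describes a solid lesion for [make_phantom()]: an axis-aligned ellipsoid
#' whose voxels draw (D_app, K_app, S0) from truncated normal distributions,
#' with an optional necrotic/cystic core fraction. Necrotic voxels are
#' converted to a free-water-like compartment (K_app = 0, high diffusivity)
#' and are excluded from the returned ROI mask, mirroring the convention of
#' drawing tumour ROIs around solid tissue only.
#'
#' @param center Length-3 voxel coordinates of the lesion centre.
#' @param radii Length-3 positive semi-axes in voxels.
#' @param d_app_mean,d_app_sd Voxel D_app distribution, mm^2/s.
#' @param k_app_mean,k_app_sd Voxel K_app distribution, unitless.
#' @param s0_mean,s0_sd Voxel S0 distribution, arbitrary signal units.
#' @param necrotic_fraction Fraction in `[0, 1]` of lesion voxels converted
#'   to the free-water compartment.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(center, radii,
                        d_app_mean, d_app_sd = 0,
                        k_app_mean, k_app_sd = 0,
                        s0_mean = 1000, s0_sd = 0,
                        necrotic_fraction = 0) {
  if (length(center) != 3 || length(radii) != 3) {
    abort("`center` and `radii` must have length 3.")
  }
  if (any(radii <= 0)) abort("`radii` must be positive.")
  if (d_app_mean <= 0) abort("`d_app_mean` must be positive.")
  if (k_app_mean < 0) abort("`k_app_mean` must be non-negative.")
  if (necrotic_fraction < 0 || necrotic_fraction > 1) {
    abort("`necrotic_fraction` must lie in [0, 1].")
  }
  structure(
    list(
      center = as.numeric(center), radii = as.numeric(radii),
      d_app_mean = d_app_mean, d_app_sd = d_app_sd,
      k_app_mean = k_app_mean, k_app_sd = k_app_sd,
      s0_mean = s0_mean, s0_sd = s0_sd,
      necrotic_fraction = necrotic_fraction
    ),
    class = "lesion_spec"
  )
}

#' Default two-lesion phantom layout
#'
#' Two solid lesions on a 48 x 48 x 12 grid: one drawn at the responder-group
#' kurtosis level (K_app mean 0.69), one at the non-responder level (0.51),
#' both at diffusivities in the 1.4-1.5e-3 mm^2/s range, the first with a 15%
#' necrotic core.
#'
#' @return List of two [lesion_spec()] objects.
#' @export
default_lesion_specs <- function() {
  list(
    lesion_spec(
      center = c(15, 16, 6), radii = c(7, 7, 4),
      d_app_mean = 1.44e-3, d_app_sd = 0.15e-3,
      k_app_mean = 0.69, k_app_sd = 0.08,
      s0_mean = 1000, s0_sd = 50, necrotic_fraction = 0.15
    ),
    lesion_spec(
      center = c(33, 31, 7), radii = c(6, 6, 3),
      d_app_mean = 1.51e-3, d_app_sd = 0.15e-3,
      k_app_mean = 0.51, k_app_sd = 0.08,
      s0_mean = 1000, s0_sd = 50, necrotic_fraction = 0
    )
  )
}

# truncated-normal draws by inverse-CDF (deterministic cost, no rejection)
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    return(rep(clip(mean, lower, upper), n))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Build a synthetic DWI phantom
#'
#' Constructs a noiseless multi-b-value DWI series from voxel-wise ground
#' truth: each lesion voxel draws (S0, D_app, K_app) from its
#' [lesion_spec()]'s truncated normals (K_app clipped at 0, D_app at 1e-5)
#' and its signal follows the kurtosis model exactly at every scheme b-value.
#' A `necrotic_fraction` of each lesion's voxels becomes free-water-like
#' (K_app = 0, D_app >= 2.5e-3 mm^2/s); those voxels carry label `-k` in the
#' truth volume and are excluded from the returned ROI mask. Background
#' voxels get a low-S0 mono-exponential compartment.
#'
#' @param grid_shape Length-3 integer grid dimensions.
#' @param lesions List of [lesion_spec()] objects; all must fit in the grid.
#' @param scheme A [bvalue_scheme()].
#' @param seed Integer seed; the phantom is a pure function of its arguments.
#' @param voxel_size Voxel dimensions in mm.
#' @return List with class `dki_phantom`: `series` (noiseless [dwi_series()]),
#'   `truth` (list of `s0_map`, `d_app_map`, `k_app_map`, `region_labels`),
#'   and `mask` (an [roi_mask()] of solid lesion voxels only).
#' @examples
#' ph <- make_phantom(seed = 1)
#' ph$mask
#' @export
make_phantom <- function(grid_shape = c(48, 48, 12),
                         lesions = default_lesion_specs(),
                         scheme = bvalue_scheme(c(100, 500, 900, 1300, 1700)),
                         seed,
                         voxel_size = c(2.7, 2.7, 6)) {
  scheme <- as_bvalue_scheme(scheme)
  if (length(lesions) == 0) abort("At least one lesion is required.")
  grid_shape <- as.integer(grid_shape)
  for (les in lesions) {
    if (any(les$center - les$radii < 1) || any(les$center + les$radii > grid_shape)) {
      abort("Lesion extends outside the grid.")
    }
  }
  withr::with_seed(seed, {
    nvox <- prod(grid_shape)
    # background: low-S0 mono-exponential (fluid-poor tissue floor)
    s0_map <- array(50, grid_shape)
    d_map <- array(2.0e-3, grid_shape)
    k_map <- array(0, grid_shape)
    labels <- array(0L, grid_shape)
    coords <- arrayInd(seq_len(nvox), grid_shape)
    for (li in seq_along(lesions)) {
      les <- lesions[[li]]
      u <- sweep(coords, 2, les$center, "-")
      u <- sweep(u, 2, les$radii, "/")
      inside <- which(rowSums(u^2) <= 1)
      n <- length(inside)
      if (n == 0) next
      s0_map[inside] <- rtruncnorm(n, les$s0_mean, les$s0_sd, lower = 1)
      d_map[inside] <- rtruncnorm(n, les$d_app_mean, les$d_app_sd, lower = 1e-5)
      k_map[inside] <- rtruncnorm(n, les$k_app_mean, les$k_app_sd, lower = 0)
      labels[inside] <- li
      n_nec <- floor(les$necrotic_fraction * n)
      if (n_nec > 0) {
        nec <- sample(inside, n_nec)
        k_map[nec] <- 0
        d_map[nec] <- rtruncnorm(n_nec, 3.0e-3, 0.1e-3, lower = 2.5e-3)
        labels[nec] <- -li
      }
    }
    b <- as.numeric(scheme)
    signal <- array(0, c(grid_shape, length(b)))
    for (bi in seq_along(b)) {
      signal[, , , bi] <- s0_map *
        exp(-b[bi] * d_map + (b[bi]^2 * d_map^2 * k_map) / 6)
    }
    mask_labels <- labels
    mask_labels[mask_labels < 0L] <- 0L
    structure(
      list(
        series = dwi_series(signal, scheme, voxel_size),
        truth = list(
          s0_map = s0_map, d_app_map = d_map, k_app_map = k_map,
          region_labels = labels
        ),
        mask = roi_mask(mask_labels)
      ),
      class = "dki_phantom"
    )
  })
}

#' @export
print.dki_phantom <- function(x, ...) {
  cat("<dki_phantom>\n")
  print(x$series)
  print(x$mask)
  n_nec <- sum(x$truth$region_labels < 0)
  if (n_nec > 0) cat(sprintf("  %d necrotic voxel(s) excluded from the mask\n", n_nec))
  invisible(x)
}

#' Add Rician magnitude noise to a DWI series
#'
#' Replaces every sample S by `sqrt((S + e1)^2 + e2^2)` with independent
#' zero-mean Gaussian `e1`, `e2` of standard deviation `sigma` — the standard
#' noise model for magnitude-reconstructed MR images. `sigma = 0` returns the
#' input unchanged; the output is a pure function of `(series, sigma, seed)`.
#'
#' @param series A [dwi_series()].
#' @param sigma Gaussian channel noise standard deviation (>= 0), in the
#'   series' signal units.
#' @param seed Integer seed.
#' @return A [dwi_series()] with noisy signal.
#' @export
add_rician_noise <- function(series, sigma, seed) {
  stopifnot(inherits(series, "dwi_series"))
  if (sigma < 0) abort("`sigma` must be non-negative.")
  if (sigma == 0) return(series)
  withr::with_seed(seed, {
    n <- length(series$signal)
    e1 <- rnorm(n, 0, sigma)
    e2 <- rnorm(n, 0, sigma)
    noisy <- sqrt((series$signal + e1)^2 + e2^2)
    dwi_series(array(noisy, dim(series$signal)), series$scheme, series$voxel_size)
  })
}
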
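#' b-value scheme of a diffusion acquisition
#'
#' A `bvalue_scheme` is the ordered set of diffusion weightings (b-values, in
#' s/mm^2) at which a DWI series was acquired. The kurtosis model has three
#' unknowns per voxel (S0, D_app, K_app), so a scheme must contain at least
#' three distinct b-values.
#'
#' @param values Numeric vector of b-values in s/mm^2; non-negative, strictly
#'   increasing, length >= 3.
#' @return A `bvalue_scheme` object (a validated numeric vector).
#' @examples
#' bvalue_scheme(c(100, 500, 900, 1300, 1700))
#' @export
bvalue_scheme <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3) {
    abort("A b-value scheme needs at least 3 b-values (3 model unknowns).")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort("b-values must be finite.")
  }
  if (any(values < 0)) {
    abort("b-values must be non-negative.")
  }
  if (any(diff(values) <= 0)) {
    abort("b-values must be strictly increasing.")
  }
  structure(values, class = "bvalue_scheme")
}

#' @export
print.bvalue_scheme <- function(x, ...) {
  cat("<bvalue_scheme> ", paste(unclass(x), collapse = ", "), " s/mm^2\n", sep = "")
  invisible(x)
}

#' Coerce to a b-value scheme
#' @param x A numeric vector or `bvalue_scheme`.
#' @return A `bvalue_scheme`.
#' @export
as_bvalue_scheme <- function(x) {
  if (inherits(x, "bvalue_scheme")) x else bvalue_scheme(x)
}

#' Multi-b-value diffusion-weighted image series
#'
#' Bundles a 4-D signal array indexed (x, y, z, b) with its [bvalue_scheme()]
#' and the voxel size in mm. The fourth axis must match the scheme length,
#' and the signal must be finite and non-negative (magnitude MRI).
#'
#' @param signal 4-D numeric array, non-negative and finite.
#' @param scheme A [bvalue_scheme()] (or numeric vector coerced to one).
#' @param voxel_size Numeric length-3 vector of voxel dimensions in mm.
#' @return A `dwi_series` object.
#' @export
dwi_series <- function(signal, scheme, voxel_size = c(1, 1, 1)) {
  scheme <- as_bvalue_scheme(scheme)
  if (!is.array(signal) || length(dim(signal)) != 4) {
    abort("`signal` must be a 4-D array indexed (x, y, z, b).")
  }
  if (dim(signal)[4] != length(scheme)) {
    abort(sprintf(
      "4th axis of `signal` (%d volumes) does not match the scheme (%d b-values).",
      dim(signal)[4], length(scheme)
    ))
  }
  if (any(!is.finite(signal))) abort("`signal` must be finite everywhere.")
  if (any(signal < 0)) abort("`signal` must be non-negative (magnitude data).")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    abort("`voxel_size` must be 3 positive lengths in mm.")
  }
  structure(
    list(signal = signal, scheme = scheme, voxel_size = voxel_size),
    class = "dwi_series"
  )
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf(
    "<dwi_series> %d x %d x %d grid, %d b-values (%s s/mm^2), voxels %s mm\n",
    d[1], d[2], d[3], d[4],
    paste(unclass(x$scheme), collapse = ", "),
    paste(format(x$voxel_size), collapse = " x ")
  ))
  invisible(x)
}

#' Labelled region-of-interest mask
#'
#' A 3-D integer label volume on the same grid as a DWI series: 0 is
#' background, positive label k marks the voxels of lesion k. Negative labels
#' are rejected; in phantom ground truth, excluded necrotic cores are recorded
#' separately (see [make_phantom()]).
#'
#' @param labels 3-D array of non-negative integer labels.
#' @param series Optional `dwi_series` to validate the grid against.
#' @return An `roi_mask` object.
#' @export
roi_mask <- function(labels, series = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3) {
    abort("`labels` must be a 3-D array.")
  }
  if (any(!is.finite(labels)) || any(labels != round(labels))) {
    abort("Mask labels must be integers.")
  }
  if (any(labels < 0)) abort("Mask labels must be non-negative.")
  if (!is.null(series)) {
    if (!identical(dim(labels), dim(series$signal)[1:3])) {
      abort(sprintf(
        "Mask grid (%s) does not match the series grid (%s).",
        paste(dim(labels), collapse = "x"),
        paste(dim(series$signal)[1:3], collapse = "x")
      ))
    }
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  ids <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  cat(sprintf(
    "<roi_mask> %s grid, %d lesion(s), %d labelled voxel(s)\n",
    paste(dim(x$labels), collapse = "x"), length(ids), sum(x$labels > 0)
  ))
  invisible(x)
}

#' Lesion labels present in a mask
#' @param mask An [roi_mask()].
#' @return Sorted integer vector of positive labels.
#' @export
lesion_ids <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  setdiff(sort(unique(as.vector(mask$labels))), 0L)
}

#' Voxel-wise parameter maps from a model fit
#'
#' Container for the fitted maps: `s0`, `d_app` (mm^2/s), `k_app` (unitless),
#' `adc` (mm^2/s) and an integer `qc` status map. `NaN` is the sentinel for
#' "no estimate"; `qc == 0` if and only if all four metrics are finite at a
#' voxel. Non-zero codes: 1 outside mask, 2 non-positive signal, 3 fit did
#' not converge.
#'
#' @param s0,d_app,k_app,adc 3-D numeric arrays on a common grid.
#' @param qc 3-D integer array of status codes.
#' @param voxel_size Numeric length-3, mm.
#' @return A `parameter_maps` object.
#' @export
parameter_maps <- function(s0, d_app, k_app, adc, qc, voxel_size = c(1, 1, 1)) {
  maps <- list(s0 = s0, d_app = d_app, k_app = k_app, adc = adc)
  dims <- lapply(c(maps, list(qc = qc)), dim)
  if (any(vapply(dims, length, 1L) != 3)) abort("All maps must be 3-D arrays.")
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    abort("All maps must share one grid.")
  }
  if (any(!is.finite(qc))) abort("`qc` must be finite integer codes.")
  storage.mode(qc) <- "integer"
  ok <- qc == 0L
  finite_all <- Reduce(`&`, lapply(maps, is.finite))
  if (!identical(as.vector(ok), as.vector(finite_all))) {
    abort("qc == 0 must coincide exactly with voxels where all four metrics are finite.")
  }
  structure(
    c(maps, list(qc = qc, voxel_size = as.numeric(voxel_size))),
    class = "parameter_maps"
  )
}

#' @export
print.parameter_maps <- function(x, ...) {
  n_ok <- sum(x$qc == 0L)
  cat(sprintf(
    "<parameter_maps> %s grid, %d fitted voxel(s) (qc = 0)\n",
    paste(dim(x$qc), collapse = "x"), n_ok
  ))
  if (n_ok > 0) {
    ok <- x$qc == 0L
    cat(sprintf(
      "  mean D_app %.3g mm^2/s, mean K_app %.3g, mean ADC %.3g mm^2/s\n",
      mean(x$d_app[ok]), mean(x$k_app[ok]), mean(x$adc[ok])
    ))
  }
  invisible(x)
}
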
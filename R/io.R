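#' Read a 4-D DWI series with its b-value sidecar
#'
#' Reads a NIfTI-1 4-D volume (one 3-D volume per b-value) and an FSL-style
#' b-value sidecar (a whitespace- or comma-separated list of b-values in
#' s/mm^2). Volumes are re-sorted so the returned scheme is strictly
#' increasing; voxel size is taken from the image header.
#'
#' @param image_path Path to a 4-D NIfTI file (`.nii` or `.nii.gz`).
#' @param bval_path Path to the b-value text file.
#' @return A [dwi_series()].
#' @export
read_dwi_series <- function(image_path, bval_path) {
  img <- RNifti::readNifti(image_path)
  arr <- strip_nifti_attrs(as.array(img))
  if (length(dim(arr)) != 4) {
    abort(sprintf("Expected a 4-D volume, got %d axes.", length(dim(arr))))
  }
  bvals <- read_bvals(bval_path)
  if (length(bvals) != dim(arr)[4]) {
    abort(sprintf(
      "b-value count (%d) does not match volume count (%d).",
      length(bvals), dim(arr)[4]
    ))
  }
  if (any(bvals < 0)) abort("Negative b-value in sidecar.")
  ord <- order(bvals)
  dwi_series(
    signal = arr[, , , ord, drop = FALSE],
    scheme = bvalue_scheme(bvals[ord]),
    voxel_size = RNifti::pixdim(img)[1:3]
  )
}

# drop niftiImage attributes so containers hold plain arrays
strip_nifti_attrs <- function(x) array(as.vector(x), dim(x))

as_nifti_vol <- function(arr, datatype, voxel_size) {
  attr(arr, "pixdim") <- as.numeric(voxel_size)
  RNifti::asNifti(arr, datatype = datatype)
}

read_bvals <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  toks <- strsplit(txt, "[,[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  if (length(vals) == 0 || anyNA(vals)) abort("Could not parse b-value file.")
  vals
}

#' Write a DWI series to NIfTI plus b-value sidecar
#'
#' Inverse of [read_dwi_series()]: stores the 4-D signal as a float64 NIfTI
#' (for exact round-trips) and the scheme as a single whitespace-separated
#' row.
#'
#' @param series A [dwi_series()].
#' @param image_path,bval_path Output paths.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_dwi_series <- function(series, image_path, bval_path) {
  stopifnot(inherits(series, "dwi_series"))
  RNifti::writeNifti(as_nifti_vol(series$signal, "double", series$voxel_size),
                     image_path)
  writeLines(paste(format(as.numeric(series$scheme), trim = TRUE), collapse = " "),
             bval_path)
  invisible(c(image_path, bval_path))
}

#' Read a lesion label mask
#'
#' Reads a 3-D integer NIfTI label volume and validates it against a DWI
#' series grid (0 = background, k > 0 = lesion k).
#'
#' @param path Path to the 3-D NIfTI mask.
#' @param series A [dwi_series()] the mask indexes into.
#' @return An [roi_mask()].
#' @export
read_roi_mask <- function(path, series) {
  arr <- strip_nifti_attrs(as.array(RNifti::readNifti(path)))
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3) abort("Mask must be a 3-D volume.")
  roi_mask(arr, series)
}

#' Write a lesion label mask
#' @param mask An [roi_mask()].
#' @param path Output NIfTI path.
#' @param voxel_size Voxel dimensions in mm recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_roi_mask <- function(mask, path, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(mask, "roi_mask"))
  RNifti::writeNifti(as_nifti_vol(mask$labels, "int32", voxel_size), path)
  invisible(path)
}

map_file_names <- c(
  s0 = "s0.nii", d_app = "d_app.nii", k_app = "k_app.nii",
  adc = "adc.nii", qc = "qc.nii"
)

#' Write parameter maps as one NIfTI volume per metric
#'
#' Writes `s0.nii`, `d_app.nii`, `k_app.nii`, `adc.nii` (float64, so values
#' round-trip bit-identically) and `qc.nii` (int32) into `out_dir`.
#' Diffusivities are stored unscaled in mm^2/s.
#'
#' @param maps A [parameter_maps()] object.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the five file paths.
#' @export
write_parameter_maps <- function(maps, out_dir) {
  stopifnot(inherits(maps, "parameter_maps"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create output directory '%s'.", out_dir))
  }
  if (file.access(out_dir, mode = 2) != 0) {
    abort(sprintf("Output directory '%s' is not writable.", out_dir))
  }
  paths <- file.path(out_dir, map_file_names)
  names(paths) <- names(map_file_names)
  for (metric in c("s0", "d_app", "k_app", "adc")) {
    RNifti::writeNifti(as_nifti_vol(maps[[metric]], "double", maps$voxel_size),
                       paths[[metric]])
  }
  RNifti::writeNifti(as_nifti_vol(maps$qc, "int32", maps$voxel_size),
                     paths[["qc"]])
  paths
}

#' Read parameter maps written by [write_parameter_maps()]
#' @param dir Directory containing the five metric volumes.
#' @return A [parameter_maps()] object.
#' @export
read_parameter_maps <- function(dir) {
  paths <- file.path(dir, map_file_names)
  missing <- !file.exists(paths)
  if (any(missing)) {
    abort(sprintf("Missing map file(s): %s", paste(map_file_names[missing], collapse = ", ")))
  }
  imgs <- lapply(paths, RNifti::readNifti)
  names(imgs) <- names(map_file_names)
  parameter_maps(
    s0 = strip_nifti_attrs(as.array(imgs$s0)),
    d_app = strip_nifti_attrs(as.array(imgs$d_app)),
    k_app = strip_nifti_attrs(as.array(imgs$k_app)),
    adc = strip_nifti_attrs(as.array(imgs$adc)),
    qc = array(as.integer(as.array(imgs$qc)), dim(as.array(imgs$qc))),
    voxel_size = RNifti::pixdim(imgs$s0)[1:3]
  )
}

response_levels <- c("responder", "non-responder", "unclassified")

#' Validate a per-patient cohort table
#'
#' Checks the columns the downstream statistics rely on: unique `patient_id`,
#' `response_class` in responder / non-responder / unclassified, `ki67_percent`
#' within 0-100. Unknown columns are preserved untouched.
#'
#' @param table A data frame with at least `patient_id` and `response_class`.
#' @return The validated table as a tibble.
#' @export
validate_cohort_table <- function(table) {
  table <- as_tibble(table)
  req <- c("patient_id", "response_class")
  missing <- setdiff(req, names(table))
  if (length(missing) > 0) {
    abort(sprintf("Cohort table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(table$patient_id)) {
    abort("Duplicate patient_id in cohort table.")
  }
  bad <- setdiff(unique(table$response_class), response_levels)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown response label(s): %s (expected %s).",
      paste(bad, collapse = ", "), paste(response_levels, collapse = ", ")
    ))
  }
  if ("ki67_percent" %in% names(table)) {
    k <- table$ki67_percent
    if (any(!is.na(k) & (k < 0 | k > 100))) abort("ki67_percent must lie in [0, 100].")
  }
  table
}

#' Read / write a cohort table (CSV)
#'
#' CSV with a header row; required columns `patient_id` and `response_class`,
#' optional histology (`cellularity_cells_per_um2`, `ki67_percent`) and
#' per-metric VOI columns. Round-trips losslessly (doubles are written at
#' full precision).
#'
#' @param path CSV path.
#' @return [read_cohort_table()]: a validated tibble.
#' @export
read_cohort_table <- function(path) {
  # read as character and convert with base R's correctly-rounded parser so
  # the write/read cycle is bit-exact for doubles
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  tb <- as_tibble(utils::type.convert(as.data.frame(tb), as.is = TRUE))
  if (nrow(tb) > 0 && "patient_id" %in% names(tb)) {
    tb$patient_id <- as.character(tb$patient_id)
  }
  validate_cohort_table(tb)
}

#' @rdname read_cohort_table
#' @param table A cohort data frame.
#' @return [write_cohort_table()]: invisibly, `path`.
#' @export
write_cohort_table <- function(table, path) {
  table <- validate_cohort_table(table)
  # doubles are serialised at 17 significant digits so the round trip is exact
  out <- dplyr::mutate(table, dplyr::across(
    dplyr::where(is.double),
    function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  ))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
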
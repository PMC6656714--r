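#' Combine all lesion ROIs into one volume of interest
#'
#' Union of every positive label in the mask: the per-patient VOI over which
#' single summary metrics are derived. Idempotent; overlapping labels count
#' each voxel once.
#'
#' @param mask An [roi_mask()] (or a logical/integer 3-D array).
#' @return A logical 3-D array marking VOI voxels.
#' @export
combine_rois_to_voi <- function(mask) {
  labels <- if (inherits(mask, "roi_mask")) mask$labels else mask
  if (!is.array(labels) || length(dim(labels)) != 3) {
    abort("`mask` must be a 3-D label volume or roi_mask.")
  }
  array(labels > 0, dim(labels))
}

#' Reduce parameter maps to single per-patient VOI metrics
#'
#' Summarises ADC, D_app and K_app over the VOI voxels whose fit succeeded
#' (`qc == 0`), using the voxel-weighted mean (default) or median. Voxels in
#' the VOI with failed fits are excluded and counted in `n_excluded`.
#'
#' @param maps A [parameter_maps()] object.
#' @param voi Logical 3-D array (e.g. from [combine_rois_to_voi()]) on the
#'   maps' grid, or an [roi_mask()].
#' @param policy `"mean"` or `"median"` reduction over voxels.
#' @return One-row tibble: `adc_voi`, `d_app_voi`, `k_app_voi`, `n_used`,
#'   `n_excluded`. Metrics are `NaN` when no voxel is usable.
#' @export
summarize_voi <- function(maps, voi, policy = c("mean", "median")) {
  stopifnot(inherits(maps, "parameter_maps"))
  policy <- match.arg(policy)
  if (inherits(voi, "roi_mask")) voi <- combine_rois_to_voi(voi)
  if (!identical(dim(voi), dim(maps$qc))) {
    abort("VOI grid does not match the maps' grid.")
  }
  use <- voi & maps$qc == 0L
  n_used <- sum(use)
  reduce <- if (policy == "mean") mean else median
  one <- function(map) if (n_used == 0) NaN else reduce(map[use])
  tibble(
    adc_voi = one(maps$adc),
    d_app_voi = one(maps$d_app),
    k_app_voi = one(maps$k_app),
    n_used = n_used,
    n_excluded = sum(voi) - n_used
  )
}

#' Assemble a per-patient record
#'
#' Pools the patient's lesion ROIs into a VOI, reduces the parameter maps to
#' single metrics and attaches response class and optional histology
#' covariates — one row of a cohort table.
#'
#' @param patient_id Unique patient identifier.
#' @param maps A [parameter_maps()] object.
#' @param mask The patient's [roi_mask()].
#' @param response_class `"responder"`, `"non-responder"` or `"unclassified"`.
#' @param cellularity_cells_per_um2,ki67_percent Optional histology values.
#' @param policy Voxel reduction policy, see [summarize_voi()].
#' @return One-row cohort tibble.
#' @export
build_patient_record <- function(patient_id, maps, mask,
                                 response_class = "unclassified",
                                 cellularity_cells_per_um2 = NA_real_,
                                 ki67_percent = NA_real_,
                                 policy = "mean") {
  if (!response_class %in% response_levels) {
    abort(sprintf("Unknown response class '%s'.", response_class))
  }
  voi <- combine_rois_to_voi(mask)
  summ <- summarize_voi(maps, voi, policy)
  if (summ$n_used == 0) {
    warn(sprintf("Patient '%s': no evaluable VOI voxel; metrics are NaN.", patient_id))
  }
  rec <- tibble(
    patient_id = as.character(patient_id),
    response_class = response_class,
    voi_voxel_count = summ$n_used,
    adc_voi = summ$adc_voi,
    d_app_voi = summ$d_app_voi,
    k_app_voi = summ$k_app_voi,
    cellularity_cells_per_um2 = cellularity_cells_per_um2,
    ki67_percent = ki67_percent
  )
  validate_cohort_table(rec)
}
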
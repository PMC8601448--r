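#' ROI mean thickness with 1 mm clipping
#'
#' ROI masks drawn on an atlas cover voxels outside a given subject's
#' cortical sheet; their near-zero thickness values would drag the ROI
#' mean down. The rule: clip the map at `clip_mm` (values strictly below
#' the threshold are zeroed, a voxel exactly at the threshold is kept)
#' and average over the remaining non-zero voxels.
#'
#' @param map a `voxel_map` (see [generate_voxel_map()]) or numeric vector
#'   of voxel thickness values (mm, >= 0).
#' @param clip_mm clipping threshold in mm; default 1.
#' @return mean thickness (mm) over retained voxels.
#' @export
roi_mean_thickness <- function(map, clip_mm = 1.0) {
  values <- if (inherits(map, "voxel_map")) map$values else as.numeric(map)
  if (length(values) == 0L) stop("voxel map is empty")
  if (any(values < 0)) stop("voxel thickness values must be non-negative")
  values[values < clip_mm] <- 0
  kept <- values[values > 0]
  if (length(kept) == 0L) {
    stop("empty ROI: all voxels fall below the ", clip_mm,
         " mm clip; check the mask/registration")
  }
  mean(kept)
}

#' Volume-weighted whole-brain mean thickness
#'
#' Global cortical thickness summarized as the ROI-volume-weighted average
#' of the 62 regional means: `sum(volume * thickness) / sum(volume)`.
#'
#' @param thickness per-ROI mean thickness (mm).
#' @param volumes per-ROI volumes (mm^3, > 0), same length.
#' @return global mean thickness (mm).
#' @export
weighted_global_thickness <- function(thickness, volumes) {
  stopifnot(length(thickness) == length(volumes), length(thickness) >= 1L)
  if (any(volumes <= 0)) stop("all ROI volumes must be positive")
  sum(volumes * thickness) / sum(volumes)
}

#' Per-subject global thickness column for a cohort
#'
#' Applies [weighted_global_thickness()] row-wise using the cohort's
#' `vol_`-prefixed volume columns. Used to check that TCP groups do not
#' differ in overall cortical thickness even when regional models
#' discriminate them.
#'
#' @param cohort a `tcp_cohort`.
#' @return numeric vector, one value per subject.
#' @export
cohort_global_thickness <- function(cohort) {
  th <- thickness_matrix(cohort)
  vol <- as.matrix(cohort$subjects[, paste0("vol_", cohort$roi_names),
                                   drop = FALSE])
  rowSums(th * vol) / rowSums(vol)
}
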
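#' Desikan-Killiany-Tourville cortical regions
#'
#' The DKT protocol parcellates each hemisphere into 31 cortical regions
#' (62 in total). These labels are the canonical predictor order used
#' throughout the package: models, selection traces and CSV columns all
#' follow this order, so coefficients are order-stable across runs.
#'
#' @return Character vector of 31 region names (one hemisphere, unprefixed).
#' @export
dkt_region_names <- function() {
  c(
    "caudal_anterior_cingulate", "caudal_middle_frontal", "cuneus",
    "entorhinal", "fusiform", "inferior_parietal", "inferior_temporal",
    "isthmus_cingulate", "lateral_occipital", "lateral_orbitofrontal",
    "lingual", "medial_orbitofrontal", "middle_temporal", "parahippocampal",
    "paracentral", "pars_opercularis", "pars_orbitalis", "pars_triangularis",
    "pericalcarine", "postcentral", "posterior_cingulate", "precentral",
    "precuneus", "rostral_anterior_cingulate", "rostral_middle_frontal",
    "superior_frontal", "superior_parietal", "superior_temporal",
    "supramarginal", "transverse_temporal", "insula"
  )
}

#' Full bilateral DKT ROI label set
#'
#' @return Character vector of 62 labels, left hemisphere (`L_`) first,
#'   then right (`R_`), each hemisphere in [dkt_region_names()] order.
#' @export
dkt_roi_names <- function() {
  base <- dkt_region_names()
  c(paste0("L_", base), paste0("R_", base))
}

#' Hemisphere tag of each DKT ROI label
#' @param roi_names character vector of `L_`/`R_`-prefixed labels.
#' @return factor with levels `L`, `R`.
#' @export
dkt_hemisphere <- function(roi_names = dkt_roi_names()) {
  factor(substr(roi_names, 1, 1), levels = c("L", "R"))
}

#' The six a priori cingulate ROIs
#'
#' Bilateral caudal anterior, rostral anterior and posterior cingulate:
#' the region set repeatedly implicated in successful-aging studies and
#' used as the localist comparison model.
#'
#' @return Character vector of 6 ROI labels.
#' @export
cingulate_roi_set <- function() {
  regions <- c("caudal_anterior_cingulate", "rostral_anterior_cingulate",
               "posterior_cingulate")
  c(paste0("L_", regions), paste0("R_", regions))
}

# Plausible per-region mean thickness (mm), in dkt_region_names() order.
# Values are field-typical adult cortical thickness: thin occipital cortex
# (~1.7 mm pericalcarine), thick entorhinal/insular cortex (~3 mm+),
# association cortex ~2.4-2.7 mm. Both hemispheres share the same mean.
dkt_typical_thickness_one_hemi <- c(
  caudal_anterior_cingulate = 2.70, caudal_middle_frontal = 2.55,
  cuneus = 1.95, entorhinal = 3.30, fusiform = 2.70,
  inferior_parietal = 2.45, inferior_temporal = 2.75,
  isthmus_cingulate = 2.40, lateral_occipital = 2.20,
  lateral_orbitofrontal = 2.65, lingual = 2.05, medial_orbitofrontal = 2.45,
  middle_temporal = 2.85, parahippocampal = 2.75, paracentral = 2.40,
  pars_opercularis = 2.60, pars_orbitalis = 2.70, pars_triangularis = 2.50,
  pericalcarine = 1.70, postcentral = 2.05, posterior_cingulate = 2.50,
  precentral = 2.55, precuneus = 2.35, rostral_anterior_cingulate = 2.85,
  rostral_middle_frontal = 2.40, superior_frontal = 2.70,
  superior_parietal = 2.20, superior_temporal = 2.80, supramarginal = 2.50,
  transverse_temporal = 2.40, insula = 3.00
)

# Plausible per-region cortical volume (mm^3, one hemisphere), same order.
dkt_typical_volume_one_hemi <- c(
  caudal_anterior_cingulate = 2100, caudal_middle_frontal = 6500,
  cuneus = 3200, entorhinal = 1900, fusiform = 9500,
  inferior_parietal = 13500, inferior_temporal = 11000,
  isthmus_cingulate = 2600, lateral_occipital = 11500,
  lateral_orbitofrontal = 7500, lingual = 6500, medial_orbitofrontal = 5000,
  middle_temporal = 11000, parahippocampal = 2200, paracentral = 3700,
  pars_opercularis = 4400, pars_orbitalis = 2300, pars_triangularis = 3900,
  pericalcarine = 2200, postcentral = 10000, posterior_cingulate = 3300,
  precentral = 13000, precuneus = 10000, rostral_anterior_cingulate = 2500,
  rostral_middle_frontal = 16000, superior_frontal = 22500,
  superior_parietal = 12500, superior_temporal = 11500,
  supramarginal = 10000, transverse_temporal = 1100, insula = 6700
)

#' Default per-ROI mean thickness (mm)
#'
#' Field-typical DKT regional means, mirrored across hemispheres.
#' All values lie in the plausible cortical range of 1.5-4.5 mm.
#'
#' @return Named numeric vector of length 62 in [dkt_roi_names()] order.
#' @export
dkt_default_mean_thickness <- function() {
  v <- c(dkt_typical_thickness_one_hemi, dkt_typical_thickness_one_hemi)
  names(v) <- dkt_roi_names()
  v
}

#' Default per-ROI cortical volume (mm^3)
#' @return Named numeric vector of length 62 in [dkt_roi_names()] order.
#' @export
dkt_default_volume <- function() {
  v <- c(dkt_typical_volume_one_hemi, dkt_typical_volume_one_hemi)
  names(v) <- dkt_roi_names()
  v
}
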
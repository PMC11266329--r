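## 511 keV attenuation maps: HU -> linear attenuation coefficient (LAC)
## conversion, four-class MRAC assignment, and the map-preparation rules
## (crop to a common external contour, fill missing tissue and internal air
## pockets with water).

#' Piecewise-linear HU to 511 keV LAC calibration curve
#'
#' @param breakpoints strictly increasing HU values.
#' @param lac_values non-negative, non-decreasing LAC values (cm^-1) at each
#'   breakpoint; the curve is linear between breakpoints and clamped outside.
#' @return Object of class `calibration_curve`.
#' @export
calibration_curve <- function(breakpoints, lac_values) {
  if (length(breakpoints) == 0)
    stop("calibration curve must have at least one breakpoint", call. = FALSE)
  if (length(breakpoints) != length(lac_values))
    stop("breakpoints and lac_values must have equal length", call. = FALSE)
  if (is.unsorted(breakpoints, strictly = TRUE))
    stop("breakpoints must be strictly increasing", call. = FALSE)
  if (any(lac_values < 0) || is.unsorted(lac_values))
    stop("lac_values must be non-negative and non-decreasing", call. = FALSE)
  structure(list(breakpoints = breakpoints, lac_values = lac_values),
            class = "calibration_curve")
}

#' Default bilinear HU-to-LAC curve
#'
#' Anchors: (-1000 HU, 0.000), (0 HU, 0.096), (1000 HU, 0.130) cm^-1 — the
#' standard air and water LAC at 511 keV with a reduced slope above water, as
#' in published bilinear transforms. Vendor curves are proprietary; this
#' stand-in is fully configurable via [calibration_curve()].
#' @return A `calibration_curve`.
#' @export
default_calibration_curve <- function() {
  calibration_curve(c(-1000, 0, 1000), c(0, 0.096, 0.130))
}

#' Default four-class MRAC LAC values
#'
#' Air 0.000, fat 0.086, soft tissue 0.096 cm^-1 (lung unused in a pelvic
#' field of view). Values lie in the range of published four-class MRAC
#' implementations; configurable.
#' @return Named numeric vector (cm^-1).
#' @export
default_mrac_lacs <- function() {
  c(air = 0, fat = 0.086, soft_tissue = 0.096)
}

#' Convert an HU volume to a 511 keV LAC volume
#'
#' Elementwise piecewise-linear interpolation of the calibration curve,
#' clamped at the end breakpoints; monotone non-decreasing in HU.
#'
#' @param hu_volume HU array.
#' @param curve a [calibration_curve()].
#' @return LAC array (cm^-1), same shape.
#' @export
hu_to_lac <- function(hu_volume, curve = default_calibration_curve()) {
  if (!inherits(curve, "calibration_curve"))
    stop("`curve` must be a calibration_curve", call. = FALSE)
  v <- stats::approx(curve$breakpoints, curve$lac_values, xout = as.vector(hu_volume),
                     method = "linear", rule = 2)$y
  array(v, dim(hu_volume) %||% length(hu_volume))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign bulk LAC values to a class volume (MRAC model)
#'
#' Pure per-voxel lookup of population-derived 511 keV LACs for each tissue
#' class; the output takes at most `length(class_lacs)` distinct values.
#'
#' @param class_volume character array of class names (e.g. from
#'   [degrade_to_mrac_labels()]).
#' @param class_lacs named numeric vector, class -> LAC (cm^-1).
#' @return LAC array.
#' @export
mrac_assign <- function(class_volume, class_lacs = default_mrac_lacs()) {
  present <- unique(as.vector(class_volume))
  missing <- setdiff(present, names(class_lacs))
  if (length(missing))
    stop("no LAC configured for class(es): ", paste(missing, collapse = ", "),
         call. = FALSE)
  array(unname(class_lacs[as.vector(class_volume)]),
        dim(class_volume) %||% length(class_volume))
}

#' Apply the map-preparation rules to a LAC volume
#'
#' All candidate maps for one patient are prepared against the same reference
#' external contour so they share an identical support: voxels outside the
#' reference body mask are set to 0; voxels inside the body whose LAC falls
#' below an air-vs-tissue cut are treated as missing tissue and set to water;
#' internal air pockets are set to water. Idempotent.
#'
#' @param lac LAC array (cm^-1), non-negative.
#' @param reference_body_mask logical array, the shared external contour.
#' @param internal_air_pockets logical array of pocket voxels (may be empty).
#' @param water_lac LAC assigned to filled voxels (default 0.096 cm^-1).
#' @param air_cut LAC below which an in-body voxel counts as missing tissue
#'   (default 0.02 cm^-1 separates air from fat on the default curve).
#' @param voxel_spacing mm per axis, carried on the map.
#' @param provenance one of "CTAC", "sCTAC", "MRAC".
#' @return Object of class `attenuation_map` with fields `lac`,
#'   `voxel_spacing`, `provenance`, `prepared`.
#' @export
prepare_map <- function(lac, reference_body_mask,
                        internal_air_pockets = array(FALSE, dim(lac)),
                        water_lac = 0.096, air_cut = 0.02,
                        voxel_spacing = c(3, 3, 3),
                        provenance = c("CTAC", "sCTAC", "MRAC")) {
  provenance <- match.arg(provenance)
  stopifnot_volume(lac)
  if (!same_grid(lac, reference_body_mask) ||
      !same_grid(lac, internal_air_pockets))
    stop("masks must share the LAC grid", call. = FALSE)
  if (!any(reference_body_mask))
    stop("reference body mask is empty", call. = FALSE)
  if (any(lac < 0)) stop("LAC volume must be non-negative", call. = FALSE)
  out <- lac
  out[!reference_body_mask] <- 0
  fill <- reference_body_mask & (out < air_cut)
  out[fill] <- water_lac
  out[internal_air_pockets & reference_body_mask] <- water_lac
  structure(list(lac = out, voxel_spacing = voxel_spacing,
                 provenance = provenance, prepared = TRUE),
            class = "attenuation_map")
}

#' @export
print.attenuation_map <- function(x, ...) {
  cat(sprintf("<attenuation_map %s>  %s, LAC range [%.4f, %.4f] cm^-1\n",
              x$provenance, paste(dim(x$lac), collapse = "x"),
              min(x$lac), max(x$lac)))
  invisible(x)
}

#' Build the three prepared attenuation maps for one patient
#'
#' Convenience wrapper assembling the CT-based gold standard (CTAC), the
#' synthetic-CT-style map (sCTAC, via [make_sct_hu()]) and the four-class
#' MRAC map (via [degrade_to_mrac_labels()] and [mrac_assign()]), each
#' passed through [prepare_map()] against the patient's body mask and air
#' pockets so all three share one external contour.
#'
#' @param patient a `digital_patient`.
#' @param curve HU-to-LAC [calibration_curve()].
#' @param mrac_lacs named class LACs for the MRAC model.
#' @param sct_bone_hu_bias,sct_bone_shift_mm synthetic-CT error knobs.
#' @param water_lac,air_cut see [prepare_map()].
#' @param sct_seed optional seed forwarded to [make_sct_hu()].
#' @return Named list of `attenuation_map`s: `CTAC`, `sCTAC`, `MRAC`.
#' @export
patient_attenuation_maps <- function(patient,
                                     curve = default_calibration_curve(),
                                     mrac_lacs = default_mrac_lacs(),
                                     sct_bone_hu_bias = 0,
                                     sct_bone_shift_mm = 0,
                                     water_lac = 0.096, air_cut = 0.02,
                                     sct_seed = NULL) {
  pockets <- patient$tissue_labels == "air_pocket"
  prep <- function(lac, prov)
    prepare_map(lac, patient$body_mask, pockets, water_lac = water_lac,
                air_cut = air_cut, voxel_spacing = patient$voxel_spacing,
                provenance = prov)
  ct_lac <- hu_to_lac(patient$hu_volume, curve)
  sct_hu <- make_sct_hu(patient, sct_bone_hu_bias, sct_bone_shift_mm,
                        seed = sct_seed)
  mr_lac <- mrac_assign(degrade_to_mrac_labels(patient), mrac_lacs)
  list(CTAC = prep(ct_lac, "CTAC"),
       sCTAC = prep(hu_to_lac(sct_hu, curve), "sCTAC"),
       MRAC = prep(mr_lac, "MRAC"))
}
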
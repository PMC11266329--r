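## NIfTI + JSON-sidecar persistence for phantoms, sinograms and SUV images.
## Volumes carry voxel spacing in the NIfTI affine; everything non-image
## (metadata, geometry, seeds) goes in JSON sidecars.

write_nifti_vol <- function(vol, path, spacing) {
  img <- RNifti::asNifti(vol * 1.0)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "spacing") <- RNifti::pixdim(img)
  arr
}

#' Write a digital patient to a directory of NIfTI volumes
#'
#' Writes `hu.nii.gz`, `labels.nii.gz` (integer codes over the tissue
#' classes), `activity.nii.gz`, `body_mask.nii.gz`, one
#' `manual_<kind>_<i>.nii.gz` per lesion, and a `patient.json` sidecar with
#' weight, dose, seed and the label coding.
#'
#' @param patient a `digital_patient`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_patient_nifti <- function(patient, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- patient$voxel_spacing
  write_nifti_vol(patient$hu_volume, file.path(dir, "hu.nii.gz"), sp)
  codes <- array(match(patient$tissue_labels, TISSUE_CLASSES),
                 dim(patient$tissue_labels))
  write_nifti_vol(codes, file.path(dir, "labels.nii.gz"), sp)
  write_nifti_vol(patient$activity_truth, file.path(dir, "activity.nii.gz"), sp)
  write_nifti_vol(patient$body_mask, file.path(dir, "body_mask.nii.gz"), sp)
  kinds <- vapply(patient$manual_volumes, `[[`, "", "kind")
  for (i in seq_along(patient$manual_volumes)) {
    write_nifti_vol(patient$manual_volumes[[i]]$mask,
                    file.path(dir, sprintf("manual_%s_%d.nii.gz", kinds[i], i)),
                    sp)
  }
  meta <- list(patient_id = patient$patient_id, weight_kg = patient$weight_kg,
               injected_dose_MBq = patient$injected_dose_MBq,
               seed = patient$seed, voxel_spacing = sp,
               label_levels = TISSUE_CLASSES,
               manual_kinds = as.list(kinds))
  jsonlite::write_json(meta, file.path(dir, "patient.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a digital patient written by [write_patient_nifti()]
#'
#' @param dir directory containing the patient volumes and sidecar.
#' @return A `digital_patient` (without the originating `spec`).
#' @export
read_patient_nifti <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "patient.json"),
                              simplifyVector = TRUE)
  hu <- read_nifti_vol(file.path(dir, "hu.nii.gz"))
  codes <- read_nifti_vol(file.path(dir, "labels.nii.gz"))
  labels <- array(meta$label_levels[as.integer(codes)], dim(codes))
  act <- read_nifti_vol(file.path(dir, "activity.nii.gz"))
  body <- read_nifti_vol(file.path(dir, "body_mask.nii.gz")) > 0.5
  kinds <- meta$manual_kinds
  manual <- lapply(seq_along(kinds), function(i) {
    m <- read_nifti_vol(file.path(dir, sprintf("manual_%s_%d.nii.gz",
                                               kinds[[i]], i))) > 0.5
    list(mask = m, kind = kinds[[i]], truth = NULL)
  })
  structure(list(patient_id = meta$patient_id, hu_volume = hu,
                 tissue_labels = labels, activity_truth = act,
                 body_mask = body, manual_volumes = manual,
                 voxel_spacing = as.numeric(meta$voxel_spacing),
                 weight_kg = meta$weight_kg,
                 injected_dose_MBq = meta$injected_dose_MBq,
                 spec = NULL, seed = meta$seed),
            class = "digital_patient")
}

#' Write a sinogram as NIfTI with a JSON geometry sidecar
#' @param sino a `sinogram`.
#' @param path output path ending in `.nii.gz`; the sidecar takes `.json`.
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(sino, path) {
  write_nifti_vol(sino$counts, path, c(1, 1, 1))
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(count_scale = sino$count_scale,
         n_angles = sino$geometry$n_angles,
         n_radial_bins = sino$geometry$n_radial_bins,
         radial_spacing_mm = sino$geometry$radial_spacing_mm),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sinogram written by [write_sinogram()]
#' @param path the `.nii.gz` path.
#' @return A `sinogram`.
#' @export
read_sinogram <- function(path) {
  side <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                              simplifyVector = TRUE)
  counts <- read_nifti_vol(path)
  attr(counts, "spacing") <- NULL
  structure(list(counts = counts, count_scale = side$count_scale,
                 geometry = scan_geometry(side$n_angles, side$n_radial_bins,
                                          side$radial_spacing_mm)),
            class = "sinogram")
}

#' Write an SUV image as NIfTI with a JSON sidecar
#' @param suv a `suv_image`.
#' @param path output `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_suv_nifti <- function(suv, path) {
  write_nifti_vol(suv$suv, path, suv$voxel_spacing)
  jsonlite::write_json(
    list(provenance = suv$provenance, patient_id = suv$patient_id,
         voxel_spacing = suv$voxel_spacing),
    sub("\\.nii(\\.gz)?$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an SUV image written by [write_suv_nifti()]
#' @param path the `.nii.gz` path.
#' @return A `suv_image`.
#' @export
read_suv_nifti <- function(path) {
  side <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                              simplifyVector = TRUE)
  vol <- read_nifti_vol(path)
  attr(vol, "spacing") <- NULL
  structure(list(suv = vol, provenance = side$provenance,
                 patient_id = side$patient_id,
                 voxel_spacing = as.numeric(side$voxel_spacing)),
            class = "suv_image")
}
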
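## Synthetic pelvic phantom cohort: seeded digital patients with bone, fat,
## soft tissue, internal air pockets and FDG-avid lesions, plus the two
## degraded anatomies (four-class MRAC-style, synthetic-CT-style) that the
## attenuation-correction evaluation compares against the CT gold standard.

TISSUE_CLASSES <- c("external_air", "fat", "soft_tissue", "bone", "air_pocket")

#' Specification of a digital pelvic phantom
#'
#' Collects every knob that defines one synthetic patient: the voxel grid,
#' a superelliptical torso cross-section with a subcutaneous fat shell,
#' pelvic-bone surrogates (axial rods), spherical FDG-avid lesions with a
#' hard plateau and one-voxel linear falloff, internal air pockets, and the
#' weight / injected-dose metadata carried through to SUV bookkeeping.
#'
#' HU defaults are typical CT values: external air -1000, fat -90, soft
#' tissue +40, cortical-bone surrogate +700, air pockets -1000.
#'
#' @param grid_shape integer vector (nx, ny, nz) of voxels per axis.
#' @param voxel_spacing numeric vector, mm per axis (default 3 mm isotropic).
#' @param body_geometry list with `semi_axes_mm` (in-plane semi-axes),
#'   `power` (superellipse exponent) and `fat_fraction` (thickness of the
#'   subcutaneous fat shell as a fraction of the semi-axes).
#' @param bone_sites list of bone surrogates; each a list with `center_mm`
#'   (in-plane, origin at volume centre), `radius_mm`, `hu_mean`, `hu_sd`.
#'   Bones are rods running through all slices.
#' @param lesion_specs list of lesions; each a list with `center_mm`
#'   (3-D, mm), `diameter_mm`, `peak_suv`, `kind` ("primary" or "nodal").
#' @param air_pockets list of spheres; each a list with `center_mm` (3-D)
#'   and `radius_mm`.
#' @param background_suv soft-tissue uptake level (SUV) inside the body.
#' @param weight_kg,injected_dose_MBq patient metadata; default dosing is
#'   3.5 MBq/kg.
#' @param hu_noise_sd Gaussian HU noise applied to fat/soft-tissue voxels.
#' @param manual_margin_mm margin added to the lesion radius to form the
#'   spherical manual tumour volume enclosing it.
#' @param hu_values named list of class HU means (air, fat, soft_tissue).
#' @param seed default RNG seed used when [generate_patient()] is called
#'   without one.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L, 11L),
                         voxel_spacing = c(3, 3, 3),
                         body_geometry = list(semi_axes_mm = c(150, 105),
                                              power = 2.5,
                                              fat_fraction = 0.18),
                         bone_sites = list(
                           list(center_mm = c(-95, -15), radius_mm = 22,
                                hu_mean = 700, hu_sd = 50),
                           list(center_mm = c(95, -15), radius_mm = 22,
                                hu_mean = 700, hu_sd = 50),
                           list(center_mm = c(0, -60), radius_mm = 25,
                                hu_mean = 700, hu_sd = 50)),
                         lesion_specs = list(
                           list(center_mm = c(0, 10, 0), diameter_mm = 22,
                                peak_suv = 8, kind = "primary"),
                           list(center_mm = c(55, 35, 0), diameter_mm = 14,
                                peak_suv = 6, kind = "nodal")),
                         air_pockets = list(
                           list(center_mm = c(0, -25, 0), radius_mm = 12)),
                         background_suv = 1.0,
                         weight_kg = 75,
                         injected_dose_MBq = 3.5 * weight_kg,
                         hu_noise_sd = 15,
                         manual_margin_mm = 7.5,
                         hu_values = list(external_air = -1000, fat = -90,
                                          soft_tissue = 40, air_pocket = -1000),
                         seed = 1L) {
  spec <- structure(
    list(grid_shape = as.integer(grid_shape), voxel_spacing = voxel_spacing,
         body_geometry = body_geometry, bone_sites = bone_sites,
         lesion_specs = lesion_specs, air_pockets = air_pockets,
         background_suv = background_suv, weight_kg = weight_kg,
         injected_dose_MBq = injected_dose_MBq, hu_noise_sd = hu_noise_sd,
         manual_margin_mm = manual_margin_mm, hu_values = hu_values,
         seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

inside_body <- function(x, y, geom) {
  a <- geom$semi_axes_mm[1]; b <- geom$semi_axes_mm[2]; p <- geom$power
  (abs(x / a)^p + abs(y / b)^p) <= 1
}

validate_phantom_spec <- function(spec) {
  if (any(spec$grid_shape <= 0L) || any(spec$voxel_spacing <= 0))
    stop("grid_shape and voxel_spacing must be strictly positive", call. = FALSE)
  if (spec$background_suv <= 0)
    stop("background_suv must be > 0", call. = FALSE)
  for (i in seq_along(spec$bone_sites)) {
    s <- spec$bone_sites[[i]]
    if (s$radius_mm <= 0)
      stop(sprintf("bone site %d: radius must be > 0", i), call. = FALSE)
    if (!inside_body(s$center_mm[1], s$center_mm[2], spec$body_geometry))
      stop(sprintf("bone site %d lies outside the body geometry", i),
           call. = FALSE)
  }
  for (i in seq_along(spec$lesion_specs)) {
    l <- spec$lesion_specs[[i]]
    if (l$diameter_mm <= 0)
      stop(sprintf("lesion %d: diameter must be > 0", i), call. = FALSE)
    if (l$peak_suv <= spec$background_suv)
      stop(sprintf("lesion %d: peak SUV must exceed background_suv", i),
           call. = FALSE)
    if (!l$kind %in% c("primary", "nodal"))
      stop(sprintf("lesion %d: kind must be 'primary' or 'nodal'", i),
           call. = FALSE)
    if (!inside_body(l$center_mm[1], l$center_mm[2], spec$body_geometry))
      stop(sprintf("lesion %d lies outside the body geometry", i),
           call. = FALSE)
  }
  for (i in seq_along(spec$air_pockets)) {
    if (spec$air_pockets[[i]]$radius_mm <= 0)
      stop(sprintf("air pocket %d: radius must be > 0", i), call. = FALSE)
  }
  invisible(spec)
}

#' Generate one digital patient from a phantom specification
#'
#' Deterministic for fixed `(spec, seed)`. The returned patient carries the
#' HU volume, tissue labels, the activity truth in SUV units (lesions as
#' plateaus at peak SUV with a one-voxel linear falloff to background), the
#' body mask, one spherical manual tumour volume per lesion, and the
#' weight/dose metadata.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed; defaults to `spec$seed`.
#' @param patient_id identifier string.
#' @return An object of class `digital_patient` with fields `hu_volume`,
#'   `tissue_labels` (character array over
#'   external_air/fat/soft_tissue/bone/air_pocket), `activity_truth`,
#'   `body_mask`, `manual_volumes` (each with `mask`, `kind`, `truth`),
#'   `voxel_spacing`, `weight_kg`, `injected_dose_MBq`, `spec`.
#' @export
generate_patient <- function(spec, seed = spec$seed, patient_id = "P01") {
  validate_phantom_spec(spec)
  d <- spec$grid_shape; sp <- spec$voxel_spacing
  g <- coord_grids(d, sp)
  X <- array(g$x, d)
  Y <- array(rep(g$y, each = d[1]), d)
  Z <- array(rep(g$z, each = d[1] * d[2]), d)

  geom <- spec$body_geometry
  body <- inside_body(X, Y, geom)
  inner <- list(semi_axes_mm = geom$semi_axes_mm * (1 - geom$fat_fraction),
                power = geom$power)
  core <- inside_body(X, Y, inner)

  labels <- array("external_air", d)
  labels[body] <- "fat"
  labels[core] <- "soft_tissue"
  for (s in spec$bone_sites) {
    m <- ((X - s$center_mm[1])^2 + (Y - s$center_mm[2])^2) <= s$radius_mm^2
    labels[m & body] <- "bone"
  }
  for (p in spec$air_pockets) {
    m <- ((X - p$center_mm[1])^2 + (Y - p$center_mm[2])^2 +
            (Z - p$center_mm[3])^2) <= p$radius_mm^2
    labels[m & body] <- "air_pocket"
  }

  out <- with_seed(seed, {
    hu <- array(spec$hu_values$external_air, d)
    hu[labels == "fat"] <- spec$hu_values$fat
    hu[labels == "soft_tissue"] <- spec$hu_values$soft_tissue
    hu[labels == "air_pocket"] <- spec$hu_values$air_pocket
    for (s in spec$bone_sites) {
      m <- labels == "bone" &
        ((X - s$center_mm[1])^2 + (Y - s$center_mm[2])^2) <= s$radius_mm^2
      hu[m] <- rnorm(sum(m), s$hu_mean, s$hu_sd)
    }
    if (spec$hu_noise_sd > 0) {
      soft <- labels %in% c("fat", "soft_tissue")
      hu[soft] <- hu[soft] + rnorm(sum(soft), 0, spec$hu_noise_sd)
    }

    act <- array(0, d)
    act[body] <- spec$background_suv
    act[labels == "air_pocket"] <- 0
    falloff <- min(sp[1:2])
    for (l in spec$lesion_specs) {
      r <- l$diameter_mm / 2
      dist <- sqrt((X - l$center_mm[1])^2 + (Y - l$center_mm[2])^2 +
                     (Z - l$center_mm[3])^2)
      core_m <- dist <= pmax(r - falloff, 0) & body
      edge_m <- dist > (r - falloff) & dist <= r & body
      act[core_m] <- l$peak_suv
      w <- (r - dist[edge_m]) / falloff
      act[edge_m] <- spec$background_suv + w * (l$peak_suv - spec$background_suv)
    }
    act[labels == "air_pocket"] <- 0
    list(hu = hu, act = act)
  })

  manual <- vector("list", length(spec$lesion_specs))
  for (i in seq_along(spec$lesion_specs)) {
    l <- spec$lesion_specs[[i]]
    r <- l$diameter_mm / 2
    dist2 <- (X - l$center_mm[1])^2 + (Y - l$center_mm[2])^2 +
      (Z - l$center_mm[3])^2
    truth <- dist2 <= r^2
    mask <- dist2 <= (r + spec$manual_margin_mm)^2
    if (!all(mask[truth]))
      stop(sprintf("lesion %d (%s): truth region not contained in its manual volume",
                   i, l$kind), call. = FALSE)
    manual[[i]] <- list(mask = mask, kind = l$kind, truth = truth)
  }
  if (length(manual) > 1) {
    for (i in seq_len(length(manual) - 1)) for (j in (i + 1):length(manual)) {
      if (any(manual[[i]]$mask & manual[[j]]$mask))
        stop(sprintf("manual volumes of lesions %d and %d overlap", i, j),
             call. = FALSE)
    }
  }

  structure(
    list(patient_id = patient_id, hu_volume = out$hu, tissue_labels = labels,
         activity_truth = out$act, body_mask = body, manual_volumes = manual,
         voxel_spacing = sp, weight_kg = spec$weight_kg,
         injected_dose_MBq = spec$injected_dose_MBq, spec = spec,
         seed = as.integer(seed)),
    class = "digital_patient")
}

#' @export
print.digital_patient <- function(x, ...) {
  d <- dim(x$hu_volume)
  cat(sprintf("<digital_patient %s>  grid %dx%dx%d @ %g mm\n", x$patient_id,
              d[1], d[2], d[3], x$voxel_spacing[1]))
  cat(sprintf("  lesions: %d (%s)\n", length(x$manual_volumes),
              paste(vapply(x$manual_volumes, `[[`, "", "kind"),
                    collapse = ", ")))
  tab <- table(x$tissue_labels)
  cat("  tissue voxels:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Generate a cohort of digital patients
#'
#' Distributes `n_primary` primary and `n_nodal` nodal lesions over
#' `n_patients` patients round-robin (lesion *i* of a kind goes to patient
#' `((i-1) mod n_patients) + 1`), so e.g. 9 primaries over 10 patients leave
#' exactly one patient without a primary. Per-patient anatomy varies by
#' seeded jitter of the template: body semi-axes, bone radii and lesion peak
#' SUVs are scaled by independent uniform factors in \[0.9, 1.1\], and lesion
#' centres receive a small (±4.5 mm) in-plane jitter. Patient sub-seeds are
#' derived from the cohort seed by a fixed linear-congruential rule, so any
#' one patient is reproducible independent of cohort size.
#'
#' @param spec_template a [phantom_spec()] used as the base anatomy.
#' @param n_patients number of patients (> 0).
#' @param n_primary,n_nodal cohort-wide lesion counts.
#' @param seed cohort master seed.
#' @return List of `digital_patient` objects.
#' @export
generate_cohort <- function(spec_template, n_patients = 10L, n_primary = 9L,
                            n_nodal = 5L, seed = 1L) {
  if (n_patients <= 0) stop("n_patients must be > 0", call. = FALSE)
  validate_phantom_spec(spec_template)
  kinds <- list(primary = "primary", nodal = "nodal")
  templates <- list(
    primary = Filter(function(l) l$kind == "primary",
                     spec_template$lesion_specs),
    nodal = Filter(function(l) l$kind == "nodal", spec_template$lesion_specs))
  if (n_primary > 0 && length(templates$primary) == 0)
    stop("spec_template has no primary lesion template", call. = FALSE)
  if (n_nodal > 0 && length(templates$nodal) == 0)
    stop("spec_template has no nodal lesion template", call. = FALSE)

  assign_round_robin <- function(n) {
    if (n == 0) return(integer(0))
    ((seq_len(n) - 1L) %% n_patients) + 1L
  }
  prim_owner <- assign_round_robin(n_primary)
  nod_owner <- assign_round_robin(n_nodal)

  lapply(seq_len(n_patients), function(p) {
    base_seed <- child_seed(seed, p)
    spec_p <- with_seed(base_seed, {
      s <- spec_template
      s$body_geometry$semi_axes_mm <-
        s$body_geometry$semi_axes_mm * runif(2, 0.9, 1.1)
      for (i in seq_along(s$bone_sites))
        s$bone_sites[[i]]$radius_mm <-
          s$bone_sites[[i]]$radius_mm * runif(1, 0.9, 1.1)
      lesions <- list()
      for (kind in c("primary", "nodal")) {
        owners <- if (kind == "primary") prim_owner else nod_owner
        n_here <- sum(owners == p)
        if (n_here == 0) next
        tmpl <- templates[[kind]][[1]]
        for (k in seq_len(n_here)) {
          l <- tmpl
          l$peak_suv <- l$peak_suv * runif(1, 0.9, 1.1)
          ## extra same-kind lesions are displaced along x to avoid overlap
          if (k > 1) l$center_mm[1] <- l$center_mm[1] +
              (-1)^k * ceiling(k / 2) * (l$diameter_mm + 2 * s$manual_margin_mm + 6)
          l$center_mm[1:2] <- l$center_mm[1:2] + runif(2, -4.5, 4.5)
          lesions[[length(lesions) + 1]] <- l
        }
      }
      s$lesion_specs <- lesions
      s
    })
    generate_patient(spec_p, seed = child_seed(base_seed, 1L),
                     patient_id = sprintf("P%02d", p))
  })
}

#' Degrade tissue labels to the four-class MRAC model
#'
#' Emulates the vendor Dixon-based segmentation in a pelvic field of view
#' (lung absent): bone is invisible to the MR model and maps to soft tissue,
#' internal air pockets are converted to the water-equivalent soft-tissue
#' class, external air maps to air, and fat/soft tissue are preserved.
#' A pure per-voxel relabelling; voxel counts are conserved.
#'
#' @param patient a `digital_patient`.
#' @return Character array over classes `air`, `fat`, `soft_tissue`.
#' @export
degrade_to_mrac_labels <- function(patient) {
  stopifnot(inherits(patient, "digital_patient"))
  map <- c(external_air = "air", fat = "fat", soft_tissue = "soft_tissue",
           bone = "soft_tissue", air_pocket = "soft_tissue")
  out <- array(map[patient$tissue_labels], dim(patient$tissue_labels))
  out
}

#' Synthetic-CT-style HU volume with controlled bone errors
#'
#' Emulates the residual errors of a learned synthetic CT: the HU volume is
#' the patient's CT except that bone receives an additive HU bias and,
#' optionally, a morphological boundary shift (positive dilates the bone
#' in-plane, negative erodes it). With `(0, 0)` the input is returned
#' unchanged. Voxels gained by dilation take the mean bone HU (plus bias);
#' voxels lost by erosion take the median soft-tissue HU.
#'
#' @param patient a `digital_patient`.
#' @param bone_hu_bias additive HU bias inside the (shifted) bone region.
#' @param bone_boundary_shift_mm boundary shift; clamped with a warning if
#'   its magnitude exceeds the largest bone radius in the spec.
#' @param seed optional RNG seed (reserved for stochastic error models;
#'   the default error model is deterministic).
#' @return HU volume (3-D array).
#' @export
make_sct_hu <- function(patient, bone_hu_bias = 0, bone_boundary_shift_mm = 0,
                        seed = NULL) {
  stopifnot(inherits(patient, "digital_patient"))
  hu <- patient$hu_volume
  if (bone_hu_bias == 0 && bone_boundary_shift_mm == 0) return(hu)
  bone <- patient$tissue_labels == "bone"
  max_r <- if (length(patient$spec$bone_sites))
    max(vapply(patient$spec$bone_sites, `[[`, 0, "radius_mm")) else 0
  if (abs(bone_boundary_shift_mm) > max_r) {
    warning("bone_boundary_shift_mm exceeds the largest bone radius; clamped")
    bone_boundary_shift_mm <- sign(bone_boundary_shift_mm) * max_r
  }
  steps <- round(abs(bone_boundary_shift_mm) / patient$voxel_spacing[1])
  new_bone <- bone
  if (steps > 0) {
    new_bone <- if (bone_boundary_shift_mm > 0)
      apply_slices(bone, dilate_slice, steps = steps) & patient$body_mask
    else apply_slices(bone, erode_slice, steps = steps)
  }
  gained <- new_bone & !bone
  lost <- bone & !new_bone
  if (any(gained)) hu[gained] <- mean(patient$hu_volume[bone])
  if (any(lost)) {
    soft <- patient$tissue_labels == "soft_tissue"
    hu[lost] <- stats::median(patient$hu_volume[soft])
  }
  hu[new_bone] <- hu[new_bone] + bone_hu_bias
  hu
}
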
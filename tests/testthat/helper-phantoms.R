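## Shared fixtures: a small phantom spec, desk-scale scan geometry, and a
## supersampled (anti-aliased) disc builder used as the analytic oracle
## input for projection and reconstruction checks. Heavier fixtures are
## memoised per test run.

tiny_spec <- function(...) {
  defaults <- list(
    grid_shape = c(64L, 64L, 5L), voxel_spacing = c(3, 3, 3),
    body_geometry = list(semi_axes_mm = c(85, 70), power = 2.5,
                         fat_fraction = 0.18),
    bone_sites = list(
      list(center_mm = c(-50, -10), radius_mm = 14, hu_mean = 700, hu_sd = 50),
      list(center_mm = c(50, -10), radius_mm = 14, hu_mean = 700, hu_sd = 50)),
    lesion_specs = list(
      list(center_mm = c(0, 10, 0), diameter_mm = 18, peak_suv = 8,
           kind = "primary"),
      list(center_mm = c(35, 25, 0), diameter_mm = 12, peak_suv = 6,
           kind = "nodal")),
    air_pockets = list(list(center_mm = c(0, -25, 0), radius_mm = 8)))
  over <- list(...)
  defaults[names(over)] <- over
  do.call(phantom_spec, defaults)
}

tiny_geom <- function() scan_geometry(n_angles = 32L, n_radial_bins = 96L,
                                      radial_spacing_mm = 3)

tiny_settings <- function(fwhm = 5)
  recon_settings(iterations = 4L, subsets = 8L, postfilter_fwhm_mm = fwhm)

## Anti-aliased disc: voxel values are the subsampled area fraction inside
## radius r, so discrete line integrals approximate the continuous ones.
aa_disc <- function(nx, ny, nz = 1L, voxel_mm = 3, r_mm, value = 1, ss = 4L) {
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  off <- (seq_len(ss) - (ss + 1) / 2) / ss
  sl <- matrix(0, nx, ny)
  for (ox in off) for (oy in off) {
    X <- (matrix(seq_len(nx), nx, ny) - cx + ox) * voxel_mm
    Y <- (matrix(seq_len(ny), nx, ny, byrow = TRUE) - cy + oy) * voxel_mm
    sl <- sl + (X^2 + Y^2 <= r_mm^2)
  }
  array(rep(sl / ss^2 * value, nz), c(nx, ny, nz))
}

disc_attenuation_map <- function(nx = 64, nz = 1, voxel_mm = 3, r_mm = 75,
                                 lac = 0.096, provenance = "CTAC") {
  vol <- aa_disc(nx, nx, nz, voxel_mm, r_mm, lac)
  structure(list(lac = vol, voxel_spacing = rep(voxel_mm, 3),
                 provenance = provenance, prepared = TRUE),
            class = "attenuation_map")
}

## One reconstructed tiny patient (all three provenances), computed once.
.fixture_cache <- new.env()

tiny_recon_fixture <- function() {
  if (!is.null(.fixture_cache$tiny)) return(.fixture_cache$tiny)
  spec <- tiny_spec()
  pat <- generate_patient(spec, seed = 42L)
  maps <- patient_attenuation_maps(pat, sct_bone_hu_bias = -30)
  geom <- tiny_geom(); rs <- tiny_settings()
  sino <- simulate_scan(pat$activity_truth, maps$CTAC, geom,
                        count_scale = 100, noise = TRUE, seed = 7L)
  suv <- lapply(names(maps), function(pr) {
    rec <- osem_reconstruct(sino, maps[[pr]], geom, rs)
    rec <- postfilter(rec, rs$postfilter_fwhm_mm, pat$voxel_spacing)
    to_suv(rec, 100, pat$weight_kg, pat$injected_dose_MBq, provenance = pr,
           patient_id = pat$patient_id, voxel_spacing = pat$voxel_spacing)
  })
  names(suv) <- names(maps)
  .fixture_cache$tiny <- list(patient = pat, maps = maps, geometry = geom,
                              settings = rs, sinogram = sino, suv = suv)
  .fixture_cache$tiny
}
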
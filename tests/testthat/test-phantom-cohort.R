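test_that("degenerate spec gives a uniform soft-tissue body with flat uptake", {
  spec <- tiny_spec(bone_sites = list(), lesion_specs = list(),
                    air_pockets = list(), hu_noise_sd = 0,
                    body_geometry = list(semi_axes_mm = c(85, 70), power = 2.5,
                                         fat_fraction = 0))
  p <- generate_patient(spec, seed = 1L)
  expect_setequal(unique(as.vector(p$tissue_labels)),
                  c("external_air", "soft_tissue"))
  expect_true(all(p$activity_truth[p$body_mask] == spec$background_suv))
  expect_true(all(p$activity_truth[!p$body_mask] == 0))
  expect_true(all(p$hu_volume[p$body_mask] == 40))
})

test_that("generation is deterministic and invariants hold", {
  spec <- tiny_spec()
  p1 <- generate_patient(spec, seed = 11L)
  p2 <- generate_patient(spec, seed = 11L)
  expect_identical(p1$hu_volume, p2$hu_volume)
  expect_identical(p1$activity_truth, p2$activity_truth)
  expect_identical(p1$tissue_labels, p2$tissue_labels)

  expect_identical(p1$body_mask, p1$tissue_labels != "external_air")
  expect_true(all(p1$activity_truth >= 0))
  expect_true(all(p1$activity_truth[!p1$body_mask] == 0))
  ## each lesion truth region sits in exactly its own manual volume
  for (mv in p1$manual_volumes) expect_true(all(mv$mask[mv$truth]))
  expect_false(any(p1$manual_volumes[[1]]$mask & p1$manual_volumes[[2]]$mask))
  ## HU ordering consistent with labels
  hu <- p1$hu_volume; lb <- p1$tissue_labels
  expect_lt(mean(hu[lb == "fat"]), mean(hu[lb == "soft_tissue"]))
  expect_lt(mean(hu[lb == "soft_tissue"]), mean(hu[lb == "bone"]))
  expect_true(all(hu[lb %in% c("external_air", "air_pocket")] == -1000))
})

test_that("lesion truth-region volume matches the analytic sphere volume", {
  ## 20 mm diameter sphere at 2 mm isotropic voxels:
  ## (4/3) pi 10^3 / 8 = 523.6 voxels
  spec <- tiny_spec(grid_shape = c(64L, 64L, 15L), voxel_spacing = c(2, 2, 2),
                    lesion_specs = list(list(center_mm = c(0, 10, 0),
                                             diameter_mm = 20, peak_suv = 8,
                                             kind = "primary")))
  p <- generate_patient(spec, seed = 3L)
  v_analytic <- (4 / 3) * pi * 10^3 / 8
  expect_lt(abs(sum(p$manual_volumes[[1]]$truth) - v_analytic) / v_analytic,
            0.10)
})

test_that("misplaced lesions raise a placement error naming the site", {
  expect_error(tiny_spec(lesion_specs = list(
    list(center_mm = c(200, 0, 0), diameter_mm = 10, peak_suv = 5,
         kind = "primary"))), "lesion 1")
  expect_error(tiny_spec(bone_sites = list(
    list(center_mm = c(0, 200), radius_mm = 10, hu_mean = 700, hu_sd = 10))),
    "bone site 1")
  expect_error(tiny_spec(lesion_specs = list(
    list(center_mm = c(0, 0, 0), diameter_mm = 10, peak_suv = 0.5,
         kind = "primary"))), "peak SUV")
})

test_that("cohort composition matches the requested lesion counts", {
  cohort <- generate_cohort(tiny_spec(), n_patients = 10, n_primary = 9,
                            n_nodal = 5, seed = 2L)
  expect_length(cohort, 10)
  kinds <- lapply(cohort, function(p)
    vapply(p$manual_volumes, `[[`, "", "kind"))
  expect_identical(sum(vapply(kinds, function(k) sum(k == "primary"), 0L)), 9L)
  expect_identical(sum(vapply(kinds, function(k) sum(k == "nodal"), 0L)), 5L)
  expect_identical(sum(vapply(kinds, function(k) !any(k == "primary"), TRUE)),
                   1L)

  lone <- generate_cohort(tiny_spec(), n_patients = 1, n_primary = 0,
                          n_nodal = 0, seed = 2L)
  expect_length(lone[[1]]$manual_volumes, 0)
  expect_error(generate_cohort(tiny_spec(), n_patients = 0), "n_patients")
})

test_that("cohort seeds change anatomy but not composition", {
  c1 <- generate_cohort(tiny_spec(), n_patients = 3, n_primary = 2,
                        n_nodal = 1, seed = 1L)
  c2 <- generate_cohort(tiny_spec(), n_patients = 3, n_primary = 2,
                        n_nodal = 1, seed = 99L)
  for (i in 1:3) {
    expect_false(identical(c1[[i]]$hu_volume, c2[[i]]$hu_volume))
    expect_identical(sort(unique(as.vector(c1[[i]]$tissue_labels))),
                     sort(unique(as.vector(c2[[i]]$tissue_labels))))
    expect_identical(length(c1[[i]]$manual_volumes),
                     length(c2[[i]]$manual_volumes))
  }
  ## same seed reproduces the cohort exactly
  c3 <- generate_cohort(tiny_spec(), n_patients = 3, n_primary = 2,
                        n_nodal = 1, seed = 1L)
  expect_identical(c1[[2]]$hu_volume, c3[[2]]$hu_volume)
})

test_that("MRAC degradation removes bone and conserves voxel counts", {
  p <- generate_patient(tiny_spec(), seed = 5L)
  mr <- degrade_to_mrac_labels(p)
  expect_setequal(unique(as.vector(mr)), c("air", "fat", "soft_tissue"))
  tab_in <- table(factor(p$tissue_labels, levels = petmrac:::TISSUE_CLASSES))
  tab_out <- table(factor(mr, levels = c("air", "fat", "soft_tissue")))
  expect_identical(sum(tab_out), sum(tab_in))
  expect_identical(unname(tab_out["soft_tissue"]),
                   unname(tab_in["soft_tissue"] + tab_in["bone"] +
                            tab_in["air_pocket"]))
  expect_identical(unname(tab_out["air"]), unname(tab_in["external_air"]))

  ## bone-free patient: pure relabelling
  pb <- generate_patient(tiny_spec(bone_sites = list(), air_pockets = list()),
                         seed = 5L)
  mrb <- degrade_to_mrac_labels(pb)
  map <- c(external_air = "air", fat = "fat", soft_tissue = "soft_tissue")
  expect_identical(as.vector(mrb), unname(map[as.vector(pb$tissue_labels)]))
})

test_that("synthetic-CT error knobs behave as an identity / bias / dilation", {
  p <- generate_patient(tiny_spec(), seed = 8L)
  expect_identical(make_sct_hu(p, 0, 0), p$hu_volume)

  bone <- p$tissue_labels == "bone"
  biased <- make_sct_hu(p, bone_hu_bias = 100)
  expect_equal(mean(biased[bone]) - mean(p$hu_volume[bone]), 100)
  expect_identical(biased[!bone], p$hu_volume[!bone])

  shifted <- make_sct_hu(p, 0, bone_boundary_shift_mm = 3)
  expect_gt(sum(shifted >= 400), sum(p$hu_volume >= 400))
  eroded <- make_sct_hu(p, 0, bone_boundary_shift_mm = -3)
  expect_lt(sum(eroded >= 400), sum(p$hu_volume >= 400))

  expect_warning(make_sct_hu(p, 0, bone_boundary_shift_mm = 50), "clamped")
})
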
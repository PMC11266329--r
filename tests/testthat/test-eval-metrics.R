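test_that("external contour thresholds and keeps the largest component", {
  body <- aa_disc(32, 32, 3, 3, 40, 1, ss = 1) > 0
  img <- array(0, dim(body)); img[body] <- 1
  expect_identical(external_contour(img, 0.05), body)
  expect_error(external_contour(img, 2), "empty")

  ## two disjoint blobs: only the larger is retained
  img2 <- array(0, c(20, 20, 1))
  img2[3:10, 3:10, 1] <- 1    # 64 voxels
  img2[15:17, 15:17, 1] <- 1  # 9 voxels
  m <- external_contour(img2, 0.5)
  expect_identical(sum(m), 64L)
  expect_true(all(which(m) %in% which(img2 > 0)))
})

test_that("percent difference maps match a brute-force oracle", {
  set.seed(7)
  d <- c(12, 11, 3)
  ref <- array(runif(prod(d), 0.5, 2), d)
  ev <- array(runif(prod(d), 0.5, 2), d)
  contour <- array(runif(prod(d)) > 0.3, d)
  ref[2, 2, 1] <- 0; contour[2, 2, 1] <- TRUE   # excluded voxel

  dm <- percent_diff_map(ev, ref, contour)
  ## brute force voxel-by-voxel
  vals <- c(); n_zero <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!contour[i, j, k]) next
    if (ref[i, j, k] > 0)
      vals <- c(vals, 100 * (ev[i, j, k] - ref[i, j, k]) / ref[i, j, k])
    else n_zero <- n_zero + 1L
  }
  expect_equal(mean(dm$values), mean(vals), tolerance = 1e-12)
  expect_identical(dm$n_ref_zero, n_zero)
  expect_identical(dm$n_contour, sum(contour))
  expect_identical(length(dm$values) + dm$n_ref_zero, dm$n_contour)

  expect_true(all(percent_diff_map(ref, ref, contour)$values == 0))
  expect_equal(percent_diff_map(1.1 * ref, ref, contour)$values,
               rep(10, length(dm$values)), tolerance = 1e-12)
})

test_that("difference histogram has 400 bins and conserves voxel counts", {
  mk <- function(vals, n_contour) structure(
    list(values = vals, n_contour = n_contour,
         n_ref_zero = n_contour - length(vals)),
    class = "suv_diff")

  h0 <- bin_histogram(list(mk(rep(0, 50), 50)))
  expect_length(h0$mean_per_bin, 400)
  expect_equal(diff(h0$bin_edges)[1], 0.5)
  zero_bin <- findInterval(0, h0$bin_edges)
  expect_equal(h0$mean_per_bin[zero_bin], 100)
  expect_equal(sum(h0$mean_per_bin), 100)
  expect_true(h0$single_patient)
  expect_true(all(h0$se_per_bin == 0))

  ## two patients in disjoint single bins: mean 50/50, SE = 50 per bin
  ## (sd of c(100, 0) is 70.71..., / sqrt(2) = 50)
  h2 <- bin_histogram(list(mk(rep(-10.1, 20), 20), mk(rep(25.3, 40), 40)))
  b1 <- findInterval(-10.1, h2$bin_edges)
  b2 <- findInterval(25.3, h2$bin_edges)
  expect_equal(h2$mean_per_bin[b1], 50)
  expect_equal(h2$mean_per_bin[b2], 50)
  expect_equal(h2$se_per_bin[b1], sd(c(100, 0)) / sqrt(2))

  ## conservation: binned fraction + out-of-range + ref-zero = contour count
  vals <- c(rep(0.2, 30), 150, -120)   # two outside +-100%
  h3 <- bin_histogram(list(mk(vals, 40)))
  binned <- sum(h3$per_patient_fraction[1, ]) * 40 / 100
  expect_equal(binned + 2 + (40 - length(vals)), 40)
})

test_that("bone ROI thresholding matches labels and removes speckle", {
  p <- generate_patient(tiny_spec(), seed = 12L)
  bm <- bone_mask(p$hu_volume, 200, min_component_voxels = 10)
  expect_identical(bm, p$tissue_labels == "bone")

  expect_warning(bone_mask(p$hu_volume, 2000), "empty")

  hu <- array(0, c(16, 16, 1))
  hu[4:9, 4:9, 1] <- 700     # 36-voxel bone
  hu[14, 14, 1] <- 700       # speckle
  m <- bone_mask(hu, 200, min_component_voxels = 10)
  expect_identical(sum(m), 36L)
  expect_false(m[14, 14, 1])
})

test_that("GTV thresholding follows 40% of SUVmax inside the manual volume", {
  d <- c(24, 24, 5)
  manual <- array(FALSE, d); manual[8:16, 8:16, 2:4] <- TRUE
  suv <- array(1, d)
  expect_identical(threshold_gtv(suv, manual), manual)

  suv2 <- array(1, d)
  suv2[10:14, 10:14, 3] <- 8
  gtv <- threshold_gtv(suv2, manual, 0.4)
  expect_identical(gtv, manual & (suv2 >= 3.2))
  expect_identical(sum(gtv), 25L)

  top <- threshold_gtv(suv2, manual, 1)
  expect_identical(which(top), which(manual & suv2 == 8))

  expect_error(threshold_gtv(array(0, d), manual), "zero")
  expect_error(threshold_gtv(suv2, array(FALSE, d)), "empty")
  expect_error(threshold_gtv(suv2, manual, 0), "fraction")
})

test_that("Dice behaves at the identities and a hand-counted overlap", {
  a <- array(FALSE, c(20, 20, 1)); b <- a
  a[1:10, 1:10, 1] <- TRUE               # |a| = 100
  b[1:10, 1:10, 1] <- TRUE
  expect_equal(dice(a, b), 1)
  b[] <- FALSE; b[1:10, 11:20, 1] <- TRUE
  expect_equal(dice(a, b), 0)
  ## |a| = |b| = 100 with 90 overlapping
  b[] <- FALSE; b[1:10, 2:11, 1] <- TRUE
  expect_equal(dice(a, b), 0.9)
  expect_equal(dice(b, a), 0.9)
  expect_error(dice(a & FALSE, b & FALSE), "empty")
})

test_that("distance to agreement is symmetric and matches hand geometry", {
  d <- c(24, 24, 1)
  a <- array(FALSE, d); a[8:16, 8:16, 1] <- TRUE
  expect_equal(unname(distance_to_agreement(a, a, 3)), c(0, 0))

  ## b exceeds a by one 3 mm voxel row on each side in y: every boundary
  ## voxel of b faces a boundary voxel of a at exactly one voxel spacing
  b <- array(FALSE, d); b[8:16, 7:17, 1] <- TRUE
  dta <- distance_to_agreement(a, b, 3)
  expect_equal(unname(dta["dta_max_mm"]), 3)
  dta_swap <- distance_to_agreement(b, a, 3)
  expect_equal(dta, dta_swap)

  ## a full concentric ring measures sqrt(2) * 3 mm at the corners
  ## (Euclidean surface distance)
  b2 <- array(FALSE, d); b2[7:17, 7:17, 1] <- TRUE
  expect_equal(unname(distance_to_agreement(a, b2, 3)["dta_max_mm"]),
               sqrt(2) * 3)

  ## translation invariance of the pair
  a3 <- array(FALSE, d); a3[10:18, 9:17, 1] <- TRUE
  b3 <- array(FALSE, d); b3[10:18, 8:18, 1] <- TRUE
  expect_equal(distance_to_agreement(a3, b3, 3),
               distance_to_agreement(a, b, 3))

  ## directed variant from a to b is one-sided
  dd <- distance_to_agreement(a, b, 3, directed = TRUE)
  expect_lte(dd["dta_mean_mm"], dta["dta_mean_mm"] + 1e-12)
  expect_error(distance_to_agreement(a, a & FALSE, 3), "non-empty")
})

test_that("per-lesion metrics respect scaling and sign conventions", {
  d <- c(24, 24, 5)
  manual <- array(FALSE, d); manual[8:16, 8:16, 2:4] <- TRUE
  base <- array(1, d); base[10:14, 10:14, 3] <- 8
  mk <- function(v, prov) structure(
    list(suv = v, provenance = prov, patient_id = "P01",
         voxel_spacing = c(3, 3, 3)), class = "suv_image")

  ## identical images: perfect agreement
  suv <- list(CTAC = mk(base, "CTAC"), sCTAC = mk(base, "sCTAC"),
              MRAC = mk(base, "MRAC"))
  g <- gtv_metrics(suv, manual, "primary", c(3, 3, 3))
  expect_equal(g$comparisons$dsc, c(1, 1))
  expect_equal(g$comparisons$dta_max_mm, c(0, 0))
  expect_equal(g$comparisons$volume_pct_diff, c(0, 0))
  expect_equal(g$comparisons$suv_max_pct_diff, c(0, 0))

  ## global 0.95 rescale: GTV voxel-identical, SUVmax shifts by exactly -5%
  suv2 <- suv; suv2$sCTAC <- mk(0.95 * base, "sCTAC")
  g2 <- gtv_metrics(suv2, manual, "primary", c(3, 3, 3))
  expect_identical(g2$gtv$sCTAC, g2$gtv$CTAC)
  r <- g2$comparisons[g2$comparisons$provenance == "sCTAC", ]
  expect_equal(r$suv_max_pct_diff, -5, tolerance = 1e-12)
  expect_equal(r$suv_mean_pct_diff, -5, tolerance = 1e-12)
  expect_equal(r$dsc, 1)

  ## a larger evaluated GTV gives a positive volume difference
  wide <- base; wide[9:15, 9:15, 3] <- 8
  suv3 <- suv; suv3$MRAC <- mk(wide, "MRAC")
  g3 <- gtv_metrics(suv3, manual, "primary", c(3, 3, 3))
  expect_gt(g3$comparisons$volume_pct_diff[
    g3$comparisons$provenance == "MRAC"], 0)
})

test_that("rescaling an SUV image scales its SUV statistics exactly", {
  fx <- tiny_recon_fixture()
  suv <- fx$suv$CTAC
  manual <- fx$patient$manual_volumes[[1]]$mask
  g1 <- threshold_gtv(suv, manual, 0.4)
  scaled <- suv; scaled$suv <- 0.95 * suv$suv
  g2 <- threshold_gtv(scaled, manual, 0.4)
  expect_identical(g1, g2)
  expect_equal(max(scaled$suv[g2]) / max(suv$suv[g1]), 0.95,
               tolerance = 1e-12)
})
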
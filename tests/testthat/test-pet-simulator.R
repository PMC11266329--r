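test_that("forward projection is linear and matches analytic chord lengths", {
  geom <- tiny_geom()
  nx <- 64; h <- 3
  zero <- array(0, c(nx, nx, 1))
  expect_true(all(forward_project(zero, geom, h) == 0))

  ## uniform unit disc, radius 75 mm: central-ray integral = 2r = 15 cm
  disc <- aa_disc(nx, nx, 1, h, 75, 1)
  sino <- forward_project(disc, geom, h)
  centre <- sino[c(48, 49), 1, 1]   # bins straddling s = 0 (at +-1.5 mm)
  chord <- 2 * sqrt(75^2 - 1.5^2) / 10
  expect_equal(unname(centre[1]), chord, tolerance = 0.02)
  expect_equal(unname(centre[2]), chord, tolerance = 0.02)

  ## additivity
  set.seed(2)
  f <- array(runif(nx * nx), c(nx, nx, 1))
  g <- array(runif(nx * nx), c(nx, nx, 1))
  expect_equal(forward_project(f + g, geom, h),
               forward_project(f, geom, h) + forward_project(g, geom, h),
               tolerance = 1e-12)
})

test_that("attenuation factors follow exp(-integral mu dl)", {
  geom <- tiny_geom()
  zero_map <- disc_attenuation_map(64, 1, 3, r_mm = 75, lac = 0)
  expect_true(all(attenuation_sinogram(zero_map, geom) == 1))

  water <- disc_attenuation_map(64, 1, 3, r_mm = 75, lac = 0.096)
  af <- attenuation_sinogram(water, geom)
  expect_true(all(af > 0 & af <= 1))
  ## central ray through a 15 cm water cylinder
  expect_equal(af[48, 1, 1], exp(-0.096 * 2 * sqrt(75^2 - 1.5^2) / 10),
               tolerance = 0.01)
  ## more material on a ray -> smaller factor
  thick <- disc_attenuation_map(64, 1, 3, r_mm = 85, lac = 0.096)
  expect_true(all(attenuation_sinogram(thick, geom) <= af + 1e-12))
})

test_that("scan simulation is deterministic and scales with count_scale", {
  geom <- tiny_geom()
  act <- aa_disc(64, 64, 1, 3, 60, 1)
  map <- disc_attenuation_map(64, 1, 3, 75, 0.096)
  clean <- simulate_scan(act, map, geom, count_scale = 50, noise = FALSE)
  expected <- 50 * attenuation_sinogram(map, geom) *
    forward_project(act, geom, 3)
  expect_equal(clean$counts, expected, tolerance = 1e-12)

  n1 <- simulate_scan(act, map, geom, 50, noise = TRUE, seed = 3)
  n2 <- simulate_scan(act, map, geom, 50, noise = TRUE, seed = 3)
  expect_identical(n1$counts, n2$counts)
  n3 <- simulate_scan(act, map, geom, 50, noise = TRUE, seed = 4)
  expect_false(identical(n1$counts, n3$counts))

  double <- simulate_scan(act, map, geom, 100, noise = FALSE)
  expect_equal(sum(double$counts), 2 * sum(clean$counts), tolerance = 1e-12)

  expect_error(simulate_scan(act, map, geom, count_scale = 0), "count_scale")
  mrac_map <- map; mrac_map$provenance <- "MRAC"
  expect_error(simulate_scan(act, mrac_map, geom), "CTAC")
})

test_that("OSEM recovers a uniform disc and stays non-negative", {
  geom <- tiny_geom(); rs <- tiny_settings(fwhm = 0)
  act <- aa_disc(64, 64, 1, 3, 60, 2.5)
  map <- disc_attenuation_map(64, 1, 3, 75, 0.096)
  sino <- simulate_scan(act, map, geom, 100, noise = FALSE)
  rec <- osem_reconstruct(sino, map, geom, rs) / 100
  inside <- aa_disc(64, 64, 1, 3, 60, 1) > 0.999
  expect_equal(mean(rec[inside]), 2.5, tolerance = 0.02)
  expect_true(all(rec >= 0))

  ## zero-count data give a zero image
  zero_sino <- sino; zero_sino$counts[] <- 0
  expect_true(all(osem_reconstruct(zero_sino, map, geom, rs) == 0))

  ## noisy reconstruction stays non-negative
  noisy <- simulate_scan(act, map, geom, 100, noise = TRUE, seed = 5)
  expect_true(all(osem_reconstruct(noisy, map, geom, rs) >= 0))

  expect_error(osem_reconstruct(sino, map, scan_geometry(30, 96, 3), rs),
               "subsets")
})

test_that("a truth-consistent initial image is an OSEM fixed point", {
  geom <- tiny_geom(); rs <- recon_settings(1L, 8L, 0)
  act <- aa_disc(64, 64, 1, 3, 60, 2)
  map <- disc_attenuation_map(64, 1, 3, 75, 0.096)
  sino <- simulate_scan(act, map, geom, 100, noise = FALSE)
  rec <- osem_reconstruct(sino, map, geom, rs, init = act * 100)
  denom <- pmax(act * 100, 1e-8)
  expect_lt(max(abs(rec - act * 100) / denom), 1e-6)
})

test_that("attenuation correction with a boneless map depresses bone uptake", {
  fx <- tiny_recon_fixture()
  geom <- fx$geometry; rs <- tiny_settings(fwhm = 0)
  rec_true <- osem_reconstruct(fx$sinogram, fx$maps$CTAC, geom, rs)
  rec_mrac <- osem_reconstruct(fx$sinogram, fx$maps$MRAC, geom, rs)
  bone <- fx$patient$tissue_labels == "bone"
  expect_lt(mean(rec_mrac[bone]), mean(rec_true[bone]))
})

test_that("Gaussian post-filter preserves mass and has the right shape", {
  vol <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(postfilter(vol, 0, 3), vol)
  sm <- postfilter(vol, 5, 3)
  expect_equal(sum(sm), sum(vol), tolerance = 1e-9)

  ## delta image -> separable Gaussian with sigma = fwhm/2.3548 voxels;
  ## oracle: normalised discrete Gaussian weights computed directly
  delta <- array(0, c(33, 33, 1)); delta[17, 17, 1] <- 1
  fwhm <- 6; h <- 2
  out <- postfilter(delta, fwhm, h)
  sig <- fwhm / 2.354820045 / h
  k <- (-ceiling(4 * sig)):ceiling(4 * sig)
  w <- exp(-k^2 / (2 * sig^2)); w <- w / sum(w)
  expect_equal(out[17, 17, 1], max(w)^2, tolerance = 1e-10)
  expect_equal(out[17 + 1, 17, 1], max(w) * w[which(k == 1)],
               tolerance = 1e-10)
  expect_equal(sum(out), 1, tolerance = 1e-9)
})

test_that("SUV conversion inverts the count scale", {
  truth <- aa_disc(32, 32, 1, 3, 30, 2)
  suv <- to_suv(truth * 80, 80, 70, 245, provenance = "CTAC")
  expect_equal(suv$suv, truth, tolerance = 1e-12)
  expect_true(all(to_suv(truth * 0, 80, 70, 245)$suv == 0))
  expect_error(to_suv(truth, 0, 70, 245), "count_scale")
  expect_error(to_suv(truth, 80, -1, 245), "weight")

  ## doubling count_scale with noise off leaves the SUV image unchanged
  geom <- tiny_geom(); rs <- tiny_settings(fwhm = 0)
  act <- aa_disc(64, 64, 1, 3, 60, 2)
  map <- disc_attenuation_map(64, 1, 3, 75, 0.096)
  suv1 <- osem_reconstruct(simulate_scan(act, map, geom, 50, FALSE),
                           map, geom, rs) / 50
  suv2 <- osem_reconstruct(simulate_scan(act, map, geom, 100, FALSE),
                           map, geom, rs) / 100
  expect_equal(suv1, suv2, tolerance = 1e-6)
})
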
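---
title: "Evaluating PET-MR attenuation correction with synthetic pelvic phantoms"
author: "petmrac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating PET-MR attenuation correction with synthetic pelvic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Quantitative PET needs an attenuation map: a volume of 511 keV linear
attenuation coefficients (LAC, cm⁻¹) used to correct each line of response
for the photons lost inside the patient. On PET-CT the map comes from the
CT itself. On PET-MR there is no CT: the standard vendor solution (MRAC)
segments a Dixon MR acquisition into air, lung, fat and soft tissue and
assigns each class a population LAC. Cortical bone is invisible to
conventional MR, so MRAC renders it as soft tissue, under-corrects rays
crossing bone, and biases standardised uptake values (SUV) downwards —
most strongly inside and near bone, which matters for pelvic tumour
quantification. Synthetic-CT (sCT) methods predict a CT-like HU volume
from MR (e.g. from zero-echo-time sequences that do capture bone) and
promise CT-grade maps without a CT.

`petmrac` reproduces the *evaluation methodology* for this problem as a
self-contained, seeded simulation: digital pelvic phantoms stand in for
patients, the three candidate maps (CT gold standard, sCT-style, MRAC-style)
are constructed per phantom with controlled degradations, a single
simulated acquisition per phantom is reconstructed once per map, and the
resulting SUV images are compared with per-voxel difference histograms,
threshold-based tumour delineation metrics and paired equivalence tests.
The point is not to reproduce any clinical cohort's numbers — those depend
on real anatomy, vendor reconstruction and a trained network — but to make
the full analysis chain executable, testable and extensible, with the
directional physics (bone removal depresses SUV, more inside bone than
globally) emerging from the simulation rather than being asserted.

## Pipeline at a glance

```r
library(petmrac)
config <- run_config(seed = 1)   # 10 patients, 9 primary + 5 nodal lesions
study  <- run_study(config)
summary(study)
plot(study, region = "whole")
render_tables(study, "study_out")
```

Each stage is exported on its own (`generate_cohort()`,
`patient_attenuation_maps()`, `simulate_scan()`, `osem_reconstruct()`,
`postfilter()`, `to_suv()`, `external_contour()`, `percent_diff_map()`,
`bin_histogram()`, `threshold_gtv()`, `dice()`, `distance_to_agreement()`,
`tost_paired()`, …), and a thin command-line driver
(`inst/cli/petmrac.R`) exposes `generate / simulate / reconstruct /
evaluate / report / run-all` subcommands exchanging NIfTI volumes with
JSON sidecars.

## The digital patient

A phantom is a stack of identical axial cross-sections (stacked-2D, by
default 128×128 voxels at 3 mm isotropic, 11 slices): a superelliptical
torso with a subcutaneous fat shell, pelvic-bone surrogates as axial rods,
spherical internal air pockets, and spherical FDG-avid lesions. Default
tissue HU are typical CT values — external air −1000, fat −90, soft
tissue +40, cortical-bone surrogate +700, pockets −1000 — with 15 HU
Gaussian noise on fat/soft tissue and per-site Gaussian spread inside
bone. The activity truth is expressed directly in SUV: background 1.0
inside the body, zero in air pockets, and lesions as hard plateaus at
peak SUV with a one-voxel linear falloff to background. The plateau makes
40%-of-maximum thresholding well conditioned and lesion volumes
analytically checkable against the sphere volume.

The default cohort is 10 patients carrying 9 primary (22 mm, peak SUV 8)
and 5 nodal (14 mm, peak SUV 6) lesions assigned round-robin, so exactly
one patient has no primary. Between-patient variation is seeded jitter:
body semi-axes, bone radii and lesion peak SUVs scale by independent
uniform factors in [0.9, 1.1] and lesion centres move by up to ±4.5 mm
in-plane. This gives non-degenerate between-patient variance, so standard
errors and the equivalence tests are exercised meaningfully. Lesion sizes
and uptake levels are package defaults chosen as typical for FDG-avid
ano-rectal disease, not fitted to any dataset; every value is a
`phantom_spec()` argument.

Each manual tumour volume — the region a consultant would contour — is the
lesion sphere dilated by 7.5 mm. Manual volumes must contain their lesion
and be pairwise disjoint; violations raise placement errors naming the
offending site.

Seeding is two-level: a cohort master seed spawns per-patient sub-seeds by
a fixed linear-congruential rule (`child_seed()`), so any single patient
is reproducible independent of cohort size, and all generation restores
the caller's RNG state.

What the generator does *not* emulate: real pelvic anatomy beyond class
composition, MR signal formation (ZTE/Dixon images are never synthesised —
only their downstream products), inter-scan registration error (the maps
are intrinsically co-registered; the sCT boundary-shift knob stands in for
residual misalignment), scatter, randoms, decay, dead time, detector
blur (PSF) and time-of-flight. Passing tests therefore demonstrate that
map errors propagate through reconstruction into SUV errors with the
right structure, not that any absolute clinical bias magnitude is
reproduced.

## The three attenuation maps

* **CTAC** (gold standard): the phantom HU volume converted through a
  piecewise-linear calibration curve. Vendor curves are proprietary; the
  default is bilinear with anchors (−1000 HU, 0.000), (0 HU, 0.096),
  (1000 HU, 0.130) cm⁻¹ — the standard air/water anchors at 511 keV with a
  reduced bone slope, fully configurable via `calibration_curve()`.
* **sCTAC**: the same conversion applied to `make_sct_hu()`, which
  perturbs only bone: an additive HU bias (default −30 HU, a small
  density under-estimate) and an optional morphological boundary shift.
  With both knobs at zero the sCT equals the CT exactly, giving an exact
  end-to-end identity that the tests pin down.
* **MRAC**: `degrade_to_mrac_labels()` maps bone and internal air pockets
  to the soft-tissue/water class (bone is invisible; pockets are filled),
  then `mrac_assign()` assigns bulk LACs — air 0.000, fat 0.086, soft
  tissue 0.096 cm⁻¹ (lung unused in a pelvic field of view). The values
  lie in the range of published four-class implementations and are
  configurable; no population value is claimed.

All three maps pass through `prepare_map()` against the same reference
body mask: voxels outside the external contour are zeroed, in-body voxels
with LAC below 0.02 cm⁻¹ (an air-vs-tissue cut that cleanly separates air
from fat on the default curve) are treated as missing tissue and set to
water, and internal air pockets are set to water. This mirrors clinical
practice of cropping all maps to one external contour and neutralising
air pockets that differ between acquisitions, and it guarantees the three
maps share an identical support. `prepare_map()` is idempotent.

## Acquisition and reconstruction

The scanner surrogate is 2-D parallel-beam, slice by slice: 64 angles
over 180°, 192 radial bins at 3 mm. Line integrals use a Joseph-style
projector — rays sampled at one-voxel steps with bilinear interpolation —
precomputed per angle as a sparse matrix, whose transpose is the matched
backprojector (a matched pair keeps EM convergent). The attenuation-factor
sinogram is `exp(-∫ μ dl)` with lengths in cm.

One acquisition per patient is simulated with the **CTAC** map as the
physical truth: expected counts are
`count_scale × attenuation factors × forward-projected activity`, with
optional Poisson noise under a per-patient seed. The default
`count_scale = 100` yields roughly 10⁶ expected counts per slice —
visible but not dominant noise for a 5-minute-bed-position-like regime.
Each sinogram is then reconstructed three times, once per correction map,
with identical data, geometry and settings — only the attenuation factors
differ, so every downstream difference is attributable to the map.

OSEM uses 4 iterations × 16 angle-interleaved subsets (subset *k* takes
angles ≡ *k* mod 16) and a 5.0 mm Gaussian post-filter, the clinical
protocol emulated at desk scale. Numerical choices: a 10⁻¹⁰ guard in the
EM ratio denominator; voxels with zero sensitivity in every subset (never
crossed by a ray) are frozen at 0 and excluded from updates; the image is
initialised uniform at 1 and is non-negative by construction. The
post-filter converts FWHM to σ = FWHM/2.3548 per axis and applies
separable 1-D convolution operators with columns renormalised to sum to
one: interior behaviour is the plain ±4σ-truncated Gaussian while the
global image sum is preserved exactly. `to_suv()` divides out
`count_scale`; because the activity truth is already in SUV units the
standard normalisation by injected dose per body mass cancels
algebraically, and weight/dose are carried as validated metadata.

The deliberate fidelity gaps — no PSF, no TOF, no scatter/randoms, 2-D
rather than fully 3-D sampling — are orthogonal to how attenuation-map
errors propagate, which is the quantity under study. Consequently
absolute SUV bias magnitudes from any clinical study are out of reach by
design, and the package's acceptance checks are closed-form physics
(central-ray attenuation within 1% of `exp(-0.096·d)`; noiseless
matched-map OSEM recovering a uniform disc mean within 2% after 4×16
updates) plus sign/ordering properties on the default cohort.

## Evaluation metrics

The external contour thresholds the CTAC SUV image at 0.05 (SUV is the
g/ml-equivalent scale, so the conventional 0.05 g ml⁻¹ cut is SUV 0.05),
keeps the largest connected component, and is reused unchanged for the
other two reconstructions. Per-voxel percentage differences
`100·(eval − CTAC)/CTAC` are computed inside the contour; voxels with
zero CTAC SUV are excluded rather than clamped, and their count is
reported — the division contract is explicit. Differences are binned into
400 half-open 0.5%-wide bins spanning ±100% (last bin closed) per
patient, expressed as a percentage of that patient's in-contour voxels,
and averaged across patients with a per-bin standard error (zero by
convention, and flagged, for a single patient). The bone region is
delineated on the CT HU volume — threshold 200 HU, connected components
below 50 voxels removed — and its histogram uses the same whole-contour
denominator so both histograms share one y-axis unit.

GTVs are thresholded at 40% of the maximum SUV inside each manual volume,
independently per reconstruction, with no connectivity filtering (every
qualifying voxel is kept; whether clinical systems filter here is
unstated, so the simpler contract was chosen). Delineation agreement uses
the volumetric Dice coefficient and the distance to agreement: symmetric
surface distances between boundary voxels (per-slice 4-connected erosion
difference, matching the stacked-2D geometry), reporting the pooled mean
and the maximum (symmetric Hausdorff) in mm, with a directed variant
available. Distances are Euclidean, so two contours one voxel ring apart
measure one voxel spacing face-on and √2 spacings at square corners.
SUVmax and SUVmean are measured inside each reconstruction's own GTV and
compared to CTAC as percentage differences; a global rescale of one image
leaves its GTV voxel-identical (the threshold is relative) and scales its
SUV statistics exactly, a property the tests assert.

## Equivalence analysis

The equivalence margin comes from a quadrature uncertainty budget: if
attenuation correction is independent of all other PET uncertainties,
the total PET-MR uncertainty is `sqrt(Δ_PETCT² + Δ_AC²)`, and the margin
is the largest Δ_AC that raises the total by no more than a tolerated
increase. With the literature PET-CT SUV repeatability of 12% and a 0.5%
tolerated increase, `derive_margin(12, 0.5)` = 3.5%.

Equivalence is tested with two one-sided paired t tests (TOST): with mean
difference m, standard error s (sample sd / √n, matching df = n − 1) and
margin Δ, the statistics are `(m + Δ)/s` and `(Δ − m)/s`, each with an
upper-tail p-value, and the reported p is the larger of the two. A
degenerate s = 0 (e.g. an exact identity chain) returns p = 0 when
|m| < Δ and 1 otherwise, with a warning surfaced in the study report.
Eight comparisons are tested (2 map types × 2 GTV kinds × 2 SUV metrics);
the corrected significance level is `base_alpha / (n_tests − 1)` —
deliberately the printed arithmetic of the emulated analysis, 0.05/7
reported as 0.007, rather than plain Bonferroni's 0.05/8 — with the
unrounded value used for decisions. The p-value is monotone in the
margin and symmetric under sign flip of the mean; both are asserted as
properties, and the implementation is cross-checked against an
independent numerical tail-integration oracle to 10⁻⁸.

## Problem sizes and determinism

The shipped defaults are deliberately desk-scale: 128² × 11 voxels at
3 mm, 64 angles, 10 patients × 3 reconstructions — the full default study
runs in well under a minute on one core, and the test suite builds all of
its fixtures programmatically at run time. Every stochastic step
(anatomy jitter, HU noise, Poisson counts) flows from one master seed
through documented sub-seed derivation, so a full `run_study()` is
bit-reproducible: the report object from two runs with the same config
and seed is `identical()`, and the report carries the config hash and
seed as provenance.

## Known limitations

* Stacked-2D geometry: bones are rods and slices are reconstructed
  independently; there is no out-of-plane ray modelling.
* The calibration curve and MRAC class LACs are literature-style
  stand-ins, not vendor values; both are configuration.
* The sCT error model (uniform bone HU bias + boundary shift) is a
  deliberately simple surrogate for a learned model's residuals.
* Nodal comparisons ride on n = 5 by default and inherit the low power
  that small samples imply — which is itself one of the phenomena the
  emulated analysis exhibits.
* DTA follows the symmetric surface-distance convention; delineation
  systems differ in their exact definition, so the directed variant is
  exposed as an option.
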
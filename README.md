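# petmrac

Simulation framework for evaluating **PET-MR attenuation correction**:
how do errors in the 511 keV attenuation map — above all the missing bone
of the standard four-class MR-based map (MRAC) — propagate into
standardised uptake values (SUV), tumour delineation and equivalence
decisions, and how close does a synthetic-CT-style map (sCTAC) come to
the CT gold standard (CTAC)?

The package is aimed at physicists and methodologists working on PET-MR
quantification who want the complete evaluation methodology — phantom
cohort, map preparation, reconstruction, contour metrics, equivalence
statistics — as reusable, seeded, tested code rather than a one-off
clinical analysis.

## What it computes

For a cohort of seeded digital pelvic phantoms (superelliptical torso,
fat shell, bone rods, air pockets, spherical FDG-avid lesions with truth
in SUV units), `petmrac`:

1. builds three prepared attenuation maps per phantom — CTAC from the HU
   volume through a bilinear HU→LAC curve; sCTAC from the same HU volume
   with controlled bone errors (HU bias, boundary shift); MRAC by
   four-class segmentation with bulk LACs (bone → soft tissue) — all
   cropped to one external contour with missing tissue and air pockets
   set to water;
2. simulates **one** attenuated parallel-beam acquisition per phantom
   (Poisson counts; the CTAC map is the physical truth) and reconstructs
   it **once per map** with OSEM (4 iterations × 16 subsets, 5.0 mm
   Gaussian post-filter), so reconstructions differ only in the
   attenuation factors;
3. compares the SUV images: per-voxel percentage differences inside the
   0.05-SUV external contour, binned into 400 bins over ±100% with
   across-patient mean ± SE, repeated inside the bone region; GTVs at
   40% of SUVmax inside manual tumour volumes, compared by Dice,
   symmetric distance to agreement, volume and SUVmax/SUVmean
   differences;
4. tests equivalence with two one-sided paired *t* tests (TOST). The
   margin comes from a quadrature uncertainty budget,

   Δ_PETMR = √(Δ_PETCT² + Δ_AC²),

   taking the largest attenuation-correction uncertainty Δ_AC that
   raises the 12% baseline PET-CT SUV repeatability by at most 0.5%:
   `derive_margin(12, 0.5) = 3.5` (%). The reported p is the larger of
   the two one-sided p-values, tested at a corrected level
   `0.05/(8 − 1) ≈ 0.007` for the 8 comparisons (2 maps × 2 GTV kinds ×
   2 SUV metrics).

## Worked example

```r
library(petmrac)
study <- run_study(run_config(seed = 1))
print(study)
```

```
<petmr_study>  10 patients, seed 1, config 262a20c7
  whole-image mean SUV difference: sCTAC -0.20%, MRAC -6.79%
  bone-region mean SUV difference: sCTAC -2.13%, MRAC -45.43%
  equivalence margin 3.50%, corrected alpha 0.007 (0.00714)
  sCTAC  primary SUVmax  n= 9  mean -0.15%  p=0.000  EQUIVALENT
  sCTAC  primary SUVmean n= 9  mean -0.14%  p=0.000  EQUIVALENT
  sCTAC  nodal   SUVmax  n= 5  mean -0.12%  p=0.000  EQUIVALENT
  sCTAC  nodal   SUVmean n= 5  mean -0.10%  p=0.000  EQUIVALENT
  MRAC   primary SUVmax  n= 9  mean -6.32%  p=1.000  not equivalent
  MRAC   primary SUVmean n= 9  mean -6.38%  p=1.000  not equivalent
  MRAC   nodal   SUVmax  n= 5  mean -5.75%  p=1.000  not equivalent
  MRAC   nodal   SUVmean n= 5  mean -5.74%  p=1.000  not equivalent
```

Reading this: removing bone from the attenuation map (MRAC) depresses
SUV everywhere (−6.8% whole-image mean) and drastically inside bone
(−45%), and its tumour SUV differences fail the ±3.5% equivalence test;
the small-error synthetic CT stays within a fraction of a percent and is
declared equivalent. Delineation is robust to either map — with

```r
summary(study)
```

the primary-GTV block shows MRAC Dice of 0.9964 ± 0.0008 (mean ± SE)
with maximum distance to agreement ≤ 3 mm, and the sCTAC GTVs identical
to CTAC. `plot(study)` draws the mean ± SE difference histograms,
`render_tables(study, "out/")` writes the CSV/JSON report, and
`run_config()` exposes every phantom, map, scanner, metric and
statistics parameter. A command-line driver with staged subcommands
(`generate`, `simulate`, `reconstruct`, `evaluate`, `report`, `run-all`)
lives at `inst/cli/petmrac.R`; volumes are exchanged as NIfTI with JSON
sidecars.

The magnitudes above are properties of the synthetic cohort (solid
+700 HU bone rods, desk-scale 2-D reconstruction); the methodology, not
any clinical cohort's numbers, is the reproducible object. See the
vignette `vignettes/attenuation-correction-evaluation.Rmd` for the
models, defaults and limitations.

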
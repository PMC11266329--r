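## Image and contour comparison metrics: external contour, per-voxel SUV
## percentage-difference maps and their cohort histogram, bone ROI,
## 40%-of-SUVmax tumour delineation, Dice, distance to agreement, and the
## per-lesion delineation/SUV summary.

#' External body contour from the reference SUV image
#'
#' Thresholds the reference (CTAC) SUV image at `threshold` and keeps the
#' largest 6-connected component. The same contour is reused unchanged for
#' all reconstructions of that patient.
#'
#' @param ref_suv a `suv_image` (the CTAC reconstruction) or a 3-D array.
#' @param threshold SUV threshold (> 0; default 0.05, i.e. 0.05 g/ml).
#' @return Logical array.
#' @export
external_contour <- function(ref_suv, threshold = 0.05) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  vol <- if (inherits(ref_suv, "suv_image")) ref_suv$suv else ref_suv
  mask <- vol >= threshold
  if (!any(mask))
    stop("external contour is empty: threshold exceeds the image maximum",
         call. = FALSE)
  largest_component(mask)
}

#' Per-voxel SUV percentage-difference map
#'
#' `100 * (eval - ref) / ref` at in-contour voxels where `ref > 0`; voxels
#' with `ref = 0` are excluded from the map and counted.
#'
#' @param eval_suv,ref_suv `suv_image`s (or arrays) on the same grid.
#' @param contour logical array, non-empty.
#' @return Object of class `suv_diff`: `values` (numeric vector of percent
#'   differences), `n_contour` (in-contour voxel count), `n_ref_zero`
#'   (excluded voxels), `index` (voxel indices of `values`).
#' @export
percent_diff_map <- function(eval_suv, ref_suv, contour) {
  ev <- if (inherits(eval_suv, "suv_image")) eval_suv$suv else eval_suv
  rf <- if (inherits(ref_suv, "suv_image")) ref_suv$suv else ref_suv
  if (!same_grid(ev, rf) || !same_grid(rf, contour))
    stop("images and contour must share one grid", call. = FALSE)
  if (!any(contour)) stop("contour is empty", call. = FALSE)
  idx <- which(contour)
  ok <- rf[idx] > 0
  structure(list(values = 100 * (ev[idx[ok]] - rf[idx[ok]]) / rf[idx[ok]],
                 n_contour = length(idx), n_ref_zero = sum(!ok),
                 index = idx[ok]),
            class = "suv_diff")
}

#' Cohort histogram of SUV percentage differences
#'
#' Bins each patient's percent differences into 400 half-open bins of width
#' 0.5% spanning -100% to +100% (last bin closed), expresses counts as a
#' percentage of that patient's in-contour voxels, and averages the
#' per-patient fractions across patients with a standard error per bin.
#' Differences outside the range are excluded, so per-patient fractions sum
#' to at most 100%.
#'
#' @param diff_maps list of [percent_diff_map()] results, one per patient.
#' @param range_pct histogram range (default `c(-100, 100)`).
#' @param n_bins number of bins (default 400).
#' @return Object of class `diff_histogram`: `bin_edges` (length
#'   `n_bins + 1`), `bin_mid`, `per_patient_fraction` (patients x bins, %),
#'   `mean_per_bin`, `se_per_bin`, `n_patients`, `single_patient` flag.
#' @export
bin_histogram <- function(diff_maps, range_pct = c(-100, 100), n_bins = 400L) {
  if (length(diff_maps) < 1) stop("need at least one patient", call. = FALSE)
  edges <- seq(range_pct[1], range_pct[2], length.out = n_bins + 1)
  frac <- t(vapply(diff_maps, function(dm) {
    v <- dm$values
    keep <- v >= range_pct[1] & v <= range_pct[2]
    v <- v[keep]
    ## half-open [lo, hi) bins, last bin closed
    bin <- findInterval(v, edges, rightmost.closed = TRUE, left.open = FALSE)
    100 * tabulate(bin, nbins = n_bins) / dm$n_contour
  }, numeric(n_bins)))
  n <- length(diff_maps)
  structure(list(
    bin_edges = edges, bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
    per_patient_fraction = frac,
    mean_per_bin = colMeans(frac),
    se_per_bin = if (n > 1) apply(frac, 2, sd) / sqrt(n) else rep(0, n_bins),
    n_patients = n, single_patient = n == 1),
    class = "diff_histogram")
}

#' Bone region of interest from an HU volume
#'
#' Thresholds the CT at `hu_threshold` and removes connected components
#' smaller than `min_component_voxels` (speckle). An empty result is allowed
#' (bone-free phantom) and raises a warning.
#'
#' @param hu_volume HU array.
#' @param hu_threshold HU cut for bone (default 200).
#' @param min_component_voxels minimum component size kept (default 50).
#' @return Logical array.
#' @export
bone_mask <- function(hu_volume, hu_threshold = 200,
                      min_component_voxels = 50L) {
  mask <- hu_volume >= hu_threshold
  if (!any(mask)) {
    warning("bone mask is empty")
    return(mask)
  }
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_component_voxels)
  out <- array(lab %in% keep, dim(hu_volume))
  if (!any(out)) warning("bone mask is empty after component filtering")
  out
}

#' Threshold-based gross tumour volume
#'
#' The GTV is the set of voxels inside the manual tumour volume whose SUV is
#' at least `fraction` of the maximum SUV within that manual volume. No
#' connectivity filtering is applied.
#'
#' @param suv a `suv_image` or array.
#' @param manual_volume non-empty logical array.
#' @param fraction threshold fraction of SUVmax (default 0.4; in (0, 1]).
#' @return Logical array (subset of `manual_volume`).
#' @export
threshold_gtv <- function(suv, manual_volume, fraction = 0.4) {
  vol <- if (inherits(suv, "suv_image")) suv$suv else suv
  if (!any(manual_volume)) stop("manual volume is empty", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  mx <- max(vol[manual_volume])
  if (mx <= 0)
    stop("SUV is zero throughout the manual volume", call. = FALSE)
  manual_volume & (vol >= fraction * mx)
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; symmetric, in \[0, 1\].
#'
#' @param a,b logical arrays on one grid, not both empty.
#' @return Scalar DSC.
#' @export
dice <- function(a, b) {
  if (!same_grid(a, b)) stop("masks must share one grid", call. = FALSE)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) stop("DSC undefined for two empty masks", call. = FALSE)
  2 * sum(a & b) / (na + nb)
}

## Boundary voxel coordinates (mm) of a mask.
boundary_coords <- function(mask, spacing) {
  idx <- which(boundary_voxels(mask), arr.ind = TRUE)
  sweep(idx, 2, spacing, `*`)
}

## For each row of `from`, distance to the nearest row of `to` (mm),
## chunked to bound memory.
nearest_distances <- function(from, to, chunk = 2000L) {
  out <- numeric(nrow(from))
  for (i0 in seq(1, nrow(from), by = chunk)) {
    i1 <- min(i0 + chunk - 1, nrow(from))
    block <- from[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(to^2), `+`) -
      2 * block %*% t(to)
    out[i0:i1] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Distance to agreement between two contours
#'
#' Surface distances between the boundary voxels of `a` and `b` (boundaries
#' by 6-connected erosion difference). The default symmetric form pools the
#' distances from each boundary voxel of `a` to the nearest boundary voxel
#' of `b` and vice versa: the mean of the pooled distances and their maximum
#' (the symmetric Hausdorff distance) are returned in mm. `directed = TRUE`
#' gives the a-to-b direction only.
#'
#' @param a,b non-empty logical arrays.
#' @param spacing mm per axis (length 3 or scalar).
#' @param directed logical; directed (a to b) instead of symmetric.
#' @return Named numeric: `dta_mean_mm`, `dta_max_mm`.
#' @export
distance_to_agreement <- function(a, b, spacing = c(3, 3, 3),
                                  directed = FALSE) {
  if (!same_grid(a, b)) stop("masks must share one grid", call. = FALSE)
  if (!any(a) || !any(b)) stop("masks must be non-empty", call. = FALSE)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  ca <- boundary_coords(a, spacing); cb <- boundary_coords(b, spacing)
  dab <- nearest_distances(ca, cb)
  pooled <- if (directed) dab else c(dab, nearest_distances(cb, ca))
  c(dta_mean_mm = mean(pooled), dta_max_mm = max(pooled))
}

#' Delineation and SUV metrics for one lesion across the three maps
#'
#' Thresholds each provenance's SUV image independently at
#' `fraction x SUVmax` inside the manual volume, then compares the sCTAC and
#' MRAC GTVs against the CTAC GTV (Dice, symmetric distance to agreement,
#' volume percent difference) and their SUVmax / SUVmean — each measured
#' inside that provenance's own GTV — as percent differences relative to
#' CTAC. Positive volume difference means the evaluated GTV is larger.
#'
#' @param suv_by_prov named list of `suv_image`s: `CTAC`, `sCTAC`, `MRAC`.
#' @param manual_volume logical array.
#' @param kind "primary" or "nodal".
#' @param spacing mm per axis.
#' @param fraction GTV threshold fraction (default 0.4).
#' @return Object of class `gtv_result`: `kind`, `gtv` (list of masks per
#'   provenance), per-provenance `suv_max` and `suv_mean`, and a data frame
#'   `comparisons` with one row per evaluated provenance (dsc, dta_mean_mm,
#'   dta_max_mm, volume_pct_diff, suv_max_pct_diff, suv_mean_pct_diff).
#' @export
gtv_metrics <- function(suv_by_prov, manual_volume, kind = "primary",
                        spacing = c(3, 3, 3), fraction = 0.4) {
  provs <- c("CTAC", "sCTAC", "MRAC")
  if (!all(provs %in% names(suv_by_prov)))
    stop("suv_by_prov must contain CTAC, sCTAC and MRAC", call. = FALSE)
  gtv <- lapply(suv_by_prov[provs], threshold_gtv, manual_volume = manual_volume,
                fraction = fraction)
  vol <- function(p) {
    img <- suv_by_prov[[p]]
    v <- if (inherits(img, "suv_image")) img$suv else img
    v
  }
  suv_max <- vapply(provs, function(p) max(vol(p)[gtv[[p]]]), 0)
  suv_mean <- vapply(provs, function(p) mean(vol(p)[gtv[[p]]]), 0)
  n_ct <- sum(gtv$CTAC)
  comp <- do.call(rbind, lapply(c("sCTAC", "MRAC"), function(p) {
    dta <- distance_to_agreement(gtv[[p]], gtv$CTAC, spacing)
    data.frame(
      provenance = p, kind = kind,
      dsc = dice(gtv[[p]], gtv$CTAC),
      dta_mean_mm = unname(dta["dta_mean_mm"]),
      dta_max_mm = unname(dta["dta_max_mm"]),
      volume_pct_diff = 100 * (sum(gtv[[p]]) - n_ct) / n_ct,
      suv_max_pct_diff = 100 * (suv_max[p] - suv_max["CTAC"]) / suv_max["CTAC"],
      suv_mean_pct_diff = 100 * (suv_mean[p] - suv_mean["CTAC"]) / suv_mean["CTAC"],
      stringsAsFactors = FALSE)
  }))
  rownames(comp) <- NULL
  structure(list(kind = kind, gtv = gtv, suv_max = suv_max,
                 suv_mean = suv_mean, comparisons = comp),
            class = "gtv_result")
}
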
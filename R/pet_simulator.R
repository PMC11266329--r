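## Desk-scale PET acquisition model: 2-D parallel-beam line integrals
## (Joseph-style bilinear-sampled rays precomputed as sparse matrices),
## attenuated Poisson data, and ordered-subset EM reconstruction with the
## attenuation factors of a chosen correction map folded into the system
## model. Stacked-2D: each axial slice is projected and reconstructed
## independently.

#' Parallel-beam scan geometry
#'
#' @param n_angles projection angles over 180 degrees; must be divisible by
#'   the OSEM subset count.
#' @param n_radial_bins detector bins per angle; must cover the body
#'   diagonal at `radial_spacing_mm`.
#' @param radial_spacing_mm detector bin spacing (mm).
#' @return Object of class `scan_geometry`.
#' @export
scan_geometry <- function(n_angles = 64L, n_radial_bins = 192L,
                          radial_spacing_mm = 3) {
  stopifnot(n_angles >= 1, n_radial_bins >= 1, radial_spacing_mm > 0)
  structure(list(n_angles = as.integer(n_angles),
                 n_radial_bins = as.integer(n_radial_bins),
                 radial_spacing_mm = radial_spacing_mm),
            class = "scan_geometry")
}

#' OSEM reconstruction settings
#'
#' Defaults mirror a clinical protocol: 4 iterations, 16 subsets, 5.0 mm
#' Gaussian post-filter.
#'
#' @param iterations full OSEM iterations (>= 1).
#' @param subsets ordered subsets (>= 1); must divide the geometry's
#'   `n_angles`.
#' @param postfilter_fwhm_mm Gaussian post-filter FWHM (mm, >= 0).
#' @param epsilon guard added to EM ratio denominators.
#' @return Object of class `recon_settings`.
#' @export
recon_settings <- function(iterations = 4L, subsets = 16L,
                           postfilter_fwhm_mm = 5.0, epsilon = 1e-10) {
  stopifnot(iterations >= 1, subsets >= 1, postfilter_fwhm_mm >= 0,
            epsilon > 0)
  structure(list(iterations = as.integer(iterations),
                 subsets = as.integer(subsets),
                 postfilter_fwhm_mm = postfilter_fwhm_mm, epsilon = epsilon),
            class = "recon_settings")
}

## ---- sparse system matrix -------------------------------------------------

.projector_cache <- new.env(parent = emptyenv())

## One angle's sparse projection matrix (n_radial_bins x nx*ny). Rays are
## sampled at one-voxel steps and bilinearly interpolated on the pixel grid;
## sample weights carry the step length in cm, so a matrix-vector product is
## the discrete line integral in image-units x cm. The transpose is the
## matched backprojector.
build_angle_matrix <- function(theta, nx, ny, voxel_mm, n_bins, radial_mm) {
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  s <- (seq_len(n_bins) - (n_bins + 1) / 2) * radial_mm
  half_diag <- sqrt((nx * voxel_mm)^2 + (ny * voxel_mm)^2) / 2
  n_t <- ceiling(2 * half_diag / voxel_mm) + 1L
  tt <- (seq_len(n_t) - (n_t + 1) / 2) * voxel_mm
  co <- cos(theta); si <- sin(theta)
  px <- as.vector(outer(s * co, -tt * si, "+")) / voxel_mm + cx
  py <- as.vector(outer(s * si, tt * co, "+")) / voxel_mm + cy
  rows <- rep(seq_len(n_bins), times = n_t)
  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0; fy <- py - y0
  step_cm <- voxel_mm / 10
  ii <- vector("list", 4); jj <- vector("list", 4); ww <- vector("list", 4)
  k <- 0L
  for (dx in 0:1) for (dy in 0:1) {
    k <- k + 1L
    xi <- x0 + dx; yi <- y0 + dy
    w <- (if (dx == 0) 1 - fx else fx) * (if (dy == 0) 1 - fy else fy)
    ok <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny & w > 0
    ii[[k]] <- rows[ok]
    jj[[k]] <- (yi[ok] - 1) * nx + xi[ok]
    ww[[k]] <- w[ok] * step_cm
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                       dims = c(n_bins, nx * ny))
}

## Per-angle matrices for a (geometry, image grid) pair, memoised.
projector_matrices <- function(geometry, nx, ny, voxel_mm) {
  key <- paste(geometry$n_angles, geometry$n_radial_bins,
               geometry$radial_spacing_mm, nx, ny, voxel_mm, sep = "_")
  if (!is.null(.projector_cache[[key]])) return(.projector_cache[[key]])
  angles <- (seq_len(geometry$n_angles) - 1) * pi / geometry$n_angles
  mats <- lapply(angles, build_angle_matrix, nx = nx, ny = ny,
                 voxel_mm = voxel_mm, n_bins = geometry$n_radial_bins,
                 radial_mm = geometry$radial_spacing_mm)
  .projector_cache[[key]] <- mats
  mats
}

#' Forward-project a volume into sinogram space
#'
#' Parallel-beam line integrals per axial slice. Linear in the image; the
#' output has units of image-units x cm.
#'
#' @param image 3-D array (or 2-D matrix treated as one slice).
#' @param geometry a [scan_geometry()].
#' @param voxel_mm in-plane voxel size (mm).
#' @return Array `(n_radial_bins, n_angles, n_slices)`.
#' @export
forward_project <- function(image, geometry, voxel_mm = 3) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  stopifnot_volume(image)
  if (any(!is.finite(image))) stop("image must be finite", call. = FALSE)
  d <- dim(image)
  mats <- projector_matrices(geometry, d[1], d[2], voxel_mm)
  out <- array(0, c(geometry$n_radial_bins, geometry$n_angles, d[3]))
  for (k in seq_len(d[3])) {
    v <- as.vector(image[, , k])
    for (a in seq_len(geometry$n_angles))
      out[, a, k] <- as.numeric(mats[[a]] %*% v)
  }
  out
}

#' Attenuation-factor sinogram of a prepared attenuation map
#'
#' `exp(-integral of LAC along each ray)`; all factors lie in (0, 1].
#'
#' @param map a prepared `attenuation_map`.
#' @param geometry a [scan_geometry()].
#' @return Array `(n_radial_bins, n_angles, n_slices)` of factors.
#' @export
attenuation_sinogram <- function(map, geometry) {
  stopifnot(inherits(map, "attenuation_map"), isTRUE(map$prepared))
  if (any(map$lac < 0)) stop("LAC must be non-negative", call. = FALSE)
  exp(-forward_project(map$lac, geometry, map$voxel_spacing[1]))
}

#' Simulate one attenuated PET acquisition
#'
#' Expected counts are `count_scale * attenuation_factors * line integrals of
#' the activity`, with the physical (CTAC) map attenuating the data. With
#' `noise = TRUE` counts are Poisson-distributed around that mean under
#' `seed`; otherwise the sinogram equals its expectation.
#'
#' @param activity activity-truth volume (SUV units).
#' @param true_map the physical `attenuation_map`; must have provenance
#'   "CTAC".
#' @param geometry a [scan_geometry()].
#' @param count_scale counts per (SUV x cm) per bin; > 0. Default gives
#'   roughly 1e6 expected counts per slice for a pelvis-sized phantom.
#' @param noise logical; Poisson noise on/off.
#' @param seed RNG seed for the noise draw.
#' @return Object of class `sinogram` with fields `counts`, `count_scale`,
#'   `geometry`.
#' @export
simulate_scan <- function(activity, true_map, geometry, count_scale = 100,
                          noise = TRUE, seed = 1L) {
  if (count_scale <= 0) stop("count_scale must be > 0", call. = FALSE)
  if (!identical(true_map$provenance, "CTAC"))
    stop("the physical truth map must have provenance CTAC", call. = FALSE)
  mean_counts <- count_scale * attenuation_sinogram(true_map, geometry) *
    forward_project(activity, geometry, true_map$voxel_spacing[1])
  counts <- if (noise) {
    with_seed(seed, array(rpois(length(mean_counts), mean_counts),
                          dim(mean_counts)))
  } else mean_counts
  structure(list(counts = counts, count_scale = count_scale,
                 geometry = geometry), class = "sinogram")
}

#' OSEM reconstruction with a chosen attenuation-correction map
#'
#' Multiplicative ordered-subset EM with the attenuation factors of
#' `correction_map` folded into the system model (subsets are
#' angle-interleaved: subset k takes angles k, k + subsets, ...). The image
#' is initialised uniform positive and stays non-negative; voxels with zero
#' sensitivity in a subset are frozen at their current value rather than
#' raising an error (and at 0 once they reach 0). Exactly
#' `iterations x subsets` sub-updates are applied. No post-filter is applied
#' here; see [postfilter()].
#'
#' @param sino a [simulate_scan()] `sinogram`.
#' @param correction_map prepared `attenuation_map` used for correction.
#' @param geometry the acquisition [scan_geometry()].
#' @param settings a [recon_settings()].
#' @param nx,ny image grid; defaults to the correction map's grid.
#' @param init optional initial image (3-D array matching the output grid);
#'   default is uniform 1 inside the field of view.
#' @return Reconstructed volume (3-D array) in `count_scale x SUV` units.
#' @export
osem_reconstruct <- function(sino, correction_map, geometry,
                             settings = recon_settings(),
                             nx = dim(correction_map$lac)[1],
                             ny = dim(correction_map$lac)[2],
                             init = NULL) {
  stopifnot(inherits(sino, "sinogram"), inherits(correction_map, "attenuation_map"),
            isTRUE(correction_map$prepared))
  if (geometry$n_angles %% settings$subsets != 0)
    stop("subsets must divide n_angles", call. = FALSE)
  d <- dim(sino$counts)
  n_slices <- d[3]
  voxel_mm <- correction_map$voxel_spacing[1]
  mats <- projector_matrices(geometry, nx, ny, voxel_mm)
  sub_angles <- lapply(seq_len(settings$subsets),
                       function(k) seq(k, geometry$n_angles, by = settings$subsets))
  A_sub <- lapply(sub_angles, function(ix) do.call(rbind, mats[ix]))
  att <- attenuation_sinogram(correction_map, geometry)
  eps <- settings$epsilon
  out <- array(0, c(nx, ny, n_slices))
  for (sl in seq_len(n_slices)) {
    y_sub <- lapply(seq_along(sub_angles), function(k)
      as.vector(sino$counts[, sub_angles[[k]], sl]))
    a_sub <- lapply(seq_along(sub_angles), function(k)
      as.vector(att[, sub_angles[[k]], sl]))
    sens <- lapply(seq_along(A_sub), function(k)
      as.numeric(Matrix::crossprod(A_sub[[k]], a_sub[[k]])))
    x <- if (is.null(init)) rep(1, nx * ny) else as.vector(init[, , sl])
    ## voxels no ray ever crosses have zero sensitivity in every subset:
    ## they are frozen at 0 and excluded from all updates
    x[Reduce(`+`, sens) == 0] <- 0
    for (it in seq_len(settings$iterations)) {
      for (k in seq_len(settings$subsets)) {
        fp <- a_sub[[k]] * as.numeric(A_sub[[k]] %*% x)
        ratio <- y_sub[[k]] / (fp + eps)
        bp <- as.numeric(Matrix::crossprod(A_sub[[k]], a_sub[[k]] * ratio))
        upd <- ifelse(sens[[k]] > 0, bp / sens[[k]], 1)
        x <- x * upd
      }
    }
    out[, , sl] <- x
  }
  out
}

## Dense 1-D Gaussian convolution operator with columns renormalised to sum
## to one: interior behaviour is the truncated (+-4 sigma) Gaussian, and the
## global sum is preserved exactly (edge columns are adaptively rescaled).
gaussian_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- (-half):half
  kern <- exp(-k^2 / (2 * sigma_vox^2))
  kern <- kern / sum(kern)
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- j + k
    ok <- idx >= 1 & idx <= n
    M[idx[ok], j] <- kern[ok]
    M[, j] <- M[, j] / sum(M[, j])
  }
  M
}

#' Gaussian post-reconstruction filter
#'
#' Separable Gaussian convolution with `sigma = fwhm / 2.3548` converted to
#' voxels per axis; the total image sum is preserved exactly. `fwhm = 0` is
#' the identity.
#'
#' @param volume 3-D array.
#' @param fwhm_mm filter full width at half maximum (mm, >= 0).
#' @param spacing mm per axis (length 3, or scalar for isotropic).
#' @return Filtered volume.
#' @export
postfilter <- function(volume, fwhm_mm, spacing = c(3, 3, 3)) {
  stopifnot_volume(volume)
  if (fwhm_mm < 0) stop("fwhm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(volume)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  d <- dim(volume)
  sig <- (fwhm_mm / 2.354820045) / spacing
  out <- volume
  ## axis 1
  M <- gaussian_conv_matrix(d[1], sig[1])
  for (k in seq_len(d[3])) out[, , k] <- M %*% out[, , k]
  ## axis 2
  M <- gaussian_conv_matrix(d[2], sig[2])
  for (k in seq_len(d[3])) out[, , k] <- out[, , k] %*% t(M)
  ## axis 3
  if (d[3] > 1) {
    M <- gaussian_conv_matrix(d[3], sig[3])
    flat <- matrix(out, nrow = d[1] * d[2], ncol = d[3])
    out <- array(flat %*% t(M), d)
  }
  out
}

#' Convert a reconstruction to SUV units
#'
#' The simulation fixes `count_scale` so that the activity truth is already
#' expressed in SUV; the standard normalisation (activity concentration x
#' body mass / injected dose) then reduces to dividing out `count_scale`.
#' Weight and dose are validated metadata carried on the image.
#'
#' @param recon reconstructed volume from [osem_reconstruct()].
#' @param count_scale the acquisition's count scale (> 0).
#' @param weight_kg,injected_dose_MBq patient metadata (> 0).
#' @param provenance correction-map provenance tag.
#' @param patient_id identifier.
#' @param voxel_spacing mm per axis.
#' @return Object of class `suv_image` with fields `suv`, `provenance`,
#'   `patient_id`, `voxel_spacing`.
#' @export
to_suv <- function(recon, count_scale, weight_kg, injected_dose_MBq,
                   provenance = c("CTAC", "sCTAC", "MRAC"),
                   patient_id = "P01", voxel_spacing = c(3, 3, 3)) {
  provenance <- match.arg(provenance)
  if (count_scale <= 0) stop("count_scale must be > 0", call. = FALSE)
  if (weight_kg <= 0 || injected_dose_MBq <= 0)
    stop("weight and injected dose must be > 0", call. = FALSE)
  structure(list(suv = recon / count_scale, provenance = provenance,
                 patient_id = patient_id, voxel_spacing = voxel_spacing),
            class = "suv_image")
}

#' @export
print.suv_image <- function(x, ...) {
  cat(sprintf("<suv_image %s/%s>  %s, SUV range [%.3f, %.3f]\n",
              x$patient_id, x$provenance, paste(dim(x$suv), collapse = "x"),
              min(x$suv), max(x$suv)))
  invisible(x)
}
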
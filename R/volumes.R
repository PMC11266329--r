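## Internal helpers shared across modules: voxel grids, morphology,
## connected components, seeded RNG scoping.

#' @importFrom stats rnorm runif rpois sd pt qnorm dt
#' @importFrom utils write.csv
NULL

## Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
## RNG state afterwards so package functions never clobber the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Deterministic per-patient sub-seed from a master seed. Linear congruential
## mix keeps results independent of cohort size and below 2^31.
child_seed <- function(master_seed, index) {
  m <- 2147483647
  s <- (as.numeric(master_seed) %% m)
  as.integer((1103515245 * s + 12345 + 2654435761 * as.numeric(index)) %% m)
}

## Voxel-centre coordinate grids in mm, origin at the volume centre.
coord_grids <- function(grid_shape, spacing) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  list(
    x = (seq_len(nx) - (nx + 1) / 2) * spacing[1],
    y = (seq_len(ny) - (ny + 1) / 2) * spacing[2],
    z = (seq_len(nz) - (nz + 1) / 2) * spacing[3]
  )
}

stopifnot_volume <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("`%s` must be a 3-D array", name), call. = FALSE)
}

same_grid <- function(a, b) identical(dim(a), dim(b))

## ---- binary morphology (stacked-2D: in-plane 4-neighbourhood) -------------

shift_slice <- function(m, dx, dy) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(FALSE, nx, ny)
  xs <- seq_len(nx) - dx; ys <- seq_len(ny) - dy
  okx <- xs >= 1 & xs <= nx; oky <- ys >= 1 & ys <= ny
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

dilate_slice <- function(m, steps) {
  for (i in seq_len(steps)) {
    m <- m | shift_slice(m, 1, 0) | shift_slice(m, -1, 0) |
      shift_slice(m, 0, 1) | shift_slice(m, 0, -1)
  }
  m
}

erode_slice <- function(m, steps) {
  for (i in seq_len(steps)) {
    m <- m & shift_slice(m, 1, 0) & shift_slice(m, -1, 0) &
      shift_slice(m, 0, 1) & shift_slice(m, 0, -1)
  }
  m
}

apply_slices <- function(vol, f, ...) {
  out <- vol
  for (k in seq_len(dim(vol)[3])) out[, , k] <- f(vol[, , k], ...)
  out
}

## 3-D binary erosion, 6-connectivity; voxels outside the grid count as
## background, so masks touching the volume edge have boundary there.
erode6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  ix <- 2:(d[1] + 1); iy <- 2:(d[2] + 1); iz <- 2:(d[3] + 1)
  sub <- function(a, b, c) pad[a, b, c, drop = FALSE]
  sub(ix, iy, iz) &
    sub(ix - 1, iy, iz) & sub(ix + 1, iy, iz) &
    sub(ix, iy - 1, iz) & sub(ix, iy + 1, iz) &
    sub(ix, iy, iz - 1) & sub(ix, iy, iz + 1)
}

## Boundary voxels of a mask: mask minus its erosion. Stacked-2D geometry:
## erosion uses the in-plane 4-neighbourhood per slice, so the boundary is
## the contour stack a slice-wise delineation system compares.
boundary_voxels <- function(mask) mask & !apply_slices(mask, erode_slice, 1L)

## ---- connected components (6-connectivity) --------------------------------

## Label foreground voxels; returns integer array, 0 = background.
label_components <- function(mask) {
  stopifnot_volume(mask)
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  nxy <- d[1] * d[2]
  edges <- list()
  ## x-neighbours: consecutive indices within a column
  nb <- idx + 1L
  keep <- ((idx - 1L) %% d[1]) + 1L < d[1]
  keep[keep] <- mask[nb[keep]]
  edges[[1]] <- cbind(idx[keep], nb[keep])
  ## y-neighbours
  nb <- idx + d[1]
  keep <- ((idx - 1L) %/% d[1]) %% d[2] + 1L < d[2]
  keep[keep] <- mask[nb[keep]]
  edges[[2]] <- cbind(idx[keep], nb[keep])
  ## z-neighbours
  nb <- idx + nxy
  keep <- ((idx - 1L) %/% nxy) + 1L < d[3]
  keep[keep] <- mask[nb[keep]]
  edges[[3]] <- cbind(idx[keep], nb[keep])
  em <- do.call(rbind, edges)
  ## map voxel indices to 1..n vertex ids
  vid <- integer(prod(d))
  vid[idx] <- seq_along(idx)
  g <- igraph::make_graph(edges = t(cbind(vid[em[, 1]], vid[em[, 2]])),
                          n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  lab[idx] <- comp$membership
  lab
}

## Largest connected component of a mask.
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (!any(lab > 0L)) return(mask & FALSE)
  tab <- tabulate(lab[lab > 0L])
  lab == which.max(tab)
}
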
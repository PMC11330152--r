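# Surface voxels of a mask: occupied voxels with at least one 6-connected
# neighbour unoccupied (mask minus 6-connected erosion). Returns arr.ind rows.
mask_surface_voxels <- function(mask) {
  m <- mask$values > 0.5
  d <- dim(m)
  shift <- function(ax, by) {
    out <- array(FALSE, d)
    n <- d[ax]
    src <- seq_len(n) - by
    ok <- src >= 1 & src <= n
    idx_to <- which(ok); idx_from <- src[ok]
    if (ax == 1) out[idx_to, , ] <- m[idx_from, , ]
    else if (ax == 2) out[, idx_to, ] <- m[, idx_from, ]
    else out[, , idx_to] <- m[, , idx_from]
    out
  }
  eroded <- m
  for (ax in 1:3) for (by in c(-1L, 1L)) eroded <- eroded & shift(ax, by)
  which(m & !eroded, arr.ind = TRUE)
}

surface_points_mm <- function(mask) {
  s <- mask_surface_voxels(mask)
  sweep(sweep(s - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |A ∩ B| / (|A| + |B|)` over voxel counts, comparing the planning
#' and propagated structures. Two empty masks count as identical (DSC 1).
#'
#' @param a,b `binary_mask`s on the same geometry (resample first otherwise).
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!same_geometry(a, b)) stop("mask geometries differ; resample first")
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0) return(1)
  2 * sum(a$values * b$values) / (na + nb)
}

#' Symmetric surface-distance statistics
#'
#' Surface voxels are each mask minus its 6-connected erosion; Euclidean
#' distances from every surface voxel of A to the nearest surface voxel of B
#' and vice versa are pooled, and their mean, SD and max reported in mm.
#'
#' @param a,b non-empty `binary_mask`s on the same geometry.
#' @export
surface_distance_stats <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!same_geometry(a, b)) stop("mask geometries differ; resample first")
  if (sum(a$values) == 0 || sum(b$values) == 0) stop("empty mask")
  pa <- surface_points_mm(a)
  pb <- surface_points_mm(b)
  d <- c(c_min_dists(pa, pb), c_min_dists(pb, pa))
  list(mean = mean(d), sd = sd(d), max = max(d))
}
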
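#' Registration configuration
#'
#' Controls the multipass B-spline deformable registration: one pass per
#' control-point spacing (coarse to fine), each minimizing mean squared
#' intensity error plus a Tikhonov penalty on the pass's control coefficients
#' by deterministic gradient descent (zero initialization, backtracking step).
#' Each pass runs on an image pyramid level with voxel spacing
#' `max(native, cp_spacing / pyramid_factor)` and is initialized from the
#' accumulated field of the previous passes.
#'
#' @param passes control-point spacings in mm, strictly decreasing.
#' @param iterations gradient-descent iterations per pass (recycled).
#' @param step_mm initial step, as the largest control-coefficient update per
#'   iteration (mm); halved on objective increase.
#' @param lambda smoothness penalty weight on mean squared control coefficients.
#' @param tol relative objective improvement below which a pass stops early.
#' @param pyramid_factor image-pyramid coarsening ratio relative to the pass's
#'   control spacing.
#' @export
registration_config <- function(passes = c(40, 20, 10), iterations = 50,
                                step_mm = 1.0, lambda = 0.02, tol = 1e-5,
                                pyramid_factor = 2) {
  if (length(passes) < 1 || any(diff(passes) >= 0))
    stop("passes must be >= 1 strictly decreasing control-point spacings")
  structure(list(passes = as.numeric(passes),
                 iterations = rep_len(as.integer(iterations), length(passes)),
                 step_mm = step_mm, lambda = lambda, tol = tol,
                 pyramid_factor = pyramid_factor),
            class = "registration_config")
}

#' Apply a rigid transform to an image
#'
#' The output voxel at world point `x` samples the input at
#' `R^-1 (x - translation)`, i.e. the image content is moved by the transform.
#' The identity transform returns the input unchanged.
#'
#' @param image a `volume_grid` or `binary_mask`.
#' @param t a [rigid_transform()].
#' @export
apply_rigid <- function(image, t) {
  stopifnot(inherits(t, "rigid_transform"))
  pts <- sweep(grid_points(image), 2, t$translation, "-")
  if (!is_identity_rotation(t)) pts <- pts %*% t$rotation  # x' R^-T = (R^-1 x')
  vals <- sample_at_points(image, pts)
  if (inherits(image, "binary_mask"))
    binary_mask(array(as.numeric(vals >= 0.5), image$dim), image$spacing, image$origin)
  else volume_grid(array(vals, image$dim), image$spacing, image$origin, fill = image$fill)
}

#' Warp an image through a displacement field
#'
#' Pull-back convention: `output(x) = moving(x + u(x))` by trilinear sampling,
#' on the fixed grid that carries the field.
#'
#' @param moving a `volume_grid` (or `binary_mask`; use [propagate_mask()] for
#'   thresholded structure propagation).
#' @param dvf a `displacement_field` on the output geometry.
#' @export
warp_image <- function(moving, dvf) {
  stopifnot(inherits(dvf, "displacement_field"))
  pts <- grid_points(dvf) + matrix(dvf$values, ncol = 3)
  vals <- sample_at_points(moving, pts)
  volume_grid(array(vals, dvf$dim), dvf$spacing, dvf$origin, fill = moving$fill)
}

#' Compose a rigid transform with a displacement field
#'
#' Returns the single field `v` whose pull-back map equals rigid-after-
#' deformable: `x + v(x) = R (x + u(x)) + t`.
#'
#' @param t a [rigid_transform()].
#' @param dvf a `displacement_field`.
#' @export
compose_rigid_dvf <- function(t, dvf) {
  stopifnot(inherits(t, "rigid_transform"), inherits(dvf, "displacement_field"))
  x <- grid_points(dvf)
  z <- x + matrix(dvf$values, ncol = 3)
  if (!is_identity_rotation(t)) z <- z %*% t(t$rotation)
  v <- sweep(z, 2, t$translation, "+") - x
  displacement_field(array(v, c(dvf$dim, 3)), dvf$spacing, dvf$origin)
}

#' Invert a displacement field
#'
#' Fixed-point iteration `v_{k+1}(y) = -u(y + v_k(y))`, valid for fields
#' without folding (positive Jacobian); `u` is extended by edge clamping so
#' the iteration stays contractive at the grid borders. Stops when the
#' largest update falls below `tol_mm`; the composition residual
#' `max |u(y + v(y)) + v(y)|` is attached as attribute `residual_mm`.
#'
#' @param dvf field to invert.
#' @param tol_mm convergence tolerance on the update (mm).
#' @param max_iter iteration cap; a warning with the residual is raised if hit.
#' @export
invert_dvf <- function(dvf, tol_mm = 0.01, max_iter = 50) {
  stopifnot(inherits(dvf, "displacement_field"))
  res <- c_invert_dvf(as.numeric(dvf$values), as.integer(dvf$dim),
                      dvf$spacing, tol_mm, as.integer(max_iter))
  if (!res$converged)
    warning(sprintf("invert_dvf: max_iter reached, composition residual %.4g mm",
                    res$residual))
  out <- displacement_field(array(res$v, c(dvf$dim, 3)), dvf$spacing, dvf$origin)
  attr(out, "residual_mm") <- res$residual
  attr(out, "iterations") <- res$iterations
  out
}

# Central-difference gradient of a 3D array along `axis` (one-sided at borders),
# divided by the voxel spacing.
array_grad <- function(arr, spacing, axis) {
  d <- dim(arr)
  n <- d[axis]
  idx_p <- pmin(seq_len(n) + 1L, n)
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  denom <- (idx_p - idx_m) * spacing
  sel <- function(i) switch(axis, arr[i, , , drop = FALSE],
                            arr[, i, , drop = FALSE], arr[, , i, drop = FALSE])
  g <- (sel(idx_p) - sel(idx_m))
  sweep(g, axis, denom, "/")
}

#' Log-Jacobian statistics of a displacement field
#'
#' The deformation gradient of `x + u(x)` is computed by central differences
#' (one-sided at the grid borders); its determinant is summarized over the
#' masked voxels as the natural log with linear-interpolation quantiles
#' (min, Q1, median, Q3, max), the max-min range (MMR) and the interquartile
#' range (IQR). Non-positive determinants (folding) are excluded with a
#' warning and counted in `n_nonpositive`.
#'
#' @param dvf a `displacement_field`.
#' @param mask a `binary_mask` on the same geometry.
#' @export
jacobian_log_stats <- function(dvf, mask) {
  stopifnot(inherits(dvf, "displacement_field"), inherits(mask, "binary_mask"))
  if (!same_geometry(dvf, mask)) stop("mask geometry must match the field")
  J <- jacobian_determinant(dvf)
  sel <- mask$values > 0.5
  if (!any(sel)) stop("empty mask")
  jv <- J[sel]
  bad <- jv <= 0
  if (any(bad)) {
    warning(sprintf("%d masked voxels with non-positive Jacobian excluded", sum(bad)))
    jv <- jv[!bad]
  }
  lj <- log(jv)
  q <- unname(quantile(lj, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  structure(list(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
                 mmr = q[5] - q[1], iqr = q[4] - q[2],
                 n_nonpositive = sum(bad)),
            class = "jacobian_stats")
}

jacobian_determinant <- function(dvf) {
  d <- dvf$dim
  u <- dvf$values
  G <- array(0, c(d, 3, 3))  # G[,,,i,j] = d u_i / d x_j
  for (i in 1:3) for (j in 1:3)
    G[, , , i, j] <- array_grad(array(u[, , , i], d), dvf$spacing[j], j)
  a11 <- 1 + G[, , , 1, 1]; a12 <- G[, , , 1, 2]; a13 <- G[, , , 1, 3]
  a21 <- G[, , , 2, 1]; a22 <- 1 + G[, , , 2, 2]; a23 <- G[, , , 2, 3]
  a31 <- G[, , , 3, 1]; a32 <- G[, , , 3, 2]; a33 <- 1 + G[, , , 3, 3]
  a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
}

#' Displacement-magnitude statistics over a mask
#'
#' Euclidean magnitude of the field per masked voxel; min, mean and max in mm
#' (the "Warp" statistics of the registration QA report).
#'
#' @inheritParams jacobian_log_stats
#' @export
displacement_stats <- function(dvf, mask) {
  stopifnot(inherits(dvf, "displacement_field"), inherits(mask, "binary_mask"))
  if (!same_geometry(dvf, mask)) stop("mask geometry must match the field")
  sel <- mask$values > 0.5
  if (!any(sel)) stop("empty mask")
  m <- sqrt(array(rowSums(matrix(dvf$values, ncol = 3)^2), dvf$dim)[sel])
  structure(list(min = min(m), mean = mean(m), max = max(m)), class = "warp_stats")
}

#' Multipass B-spline deformable registration
#'
#' Estimates the displacement field `u` with `fixed(x) ~ moving(x + u(x))` by
#' minimizing mean squared intensity error plus a smoothness penalty over
#' successive control-point resolutions, each pass initialized from the
#' previous. Fully deterministic (zero initialization, fixed schedule).
#'
#' @param fixed,moving `volume_grid`s with overlapping fields of view.
#' @param cfg a [registration_config()].
#' @return a `displacement_field` on the fixed grid, with attribute
#'   `objective_log` (per-pass objective traces).
#' @export
bspline_register <- function(fixed, moving, cfg = registration_config()) {
  stopifnot(inherits(fixed, "volume_grid"), inherits(moving, "volume_grid"))
  if (!all(is.finite(fixed$values)) || !all(is.finite(moving$values)))
    stop("non-finite intensities")
  passes <- list()
  logs <- list()
  for (p in seq_along(cfg$passes)) {
    cp <- cfg$passes[p]
    sp <- pmax(fixed$spacing, cp / cfg$pyramid_factor)
    geom <- coarse_geometry(fixed, sp)
    fx <- resample_to(fixed, geom)
    layouts <- control_layout(geom, cp)
    Bx <- basis_matrix(axis_coords(geom, 1), layouts[[1]])
    By <- basis_matrix(axis_coords(geom, 2), layouts[[2]])
    Bz <- basis_matrix(axis_coords(geom, 3), layouts[[3]])
    base_pts <- grid_points(geom)
    u_prev <- eval_passes(passes, geom)
    # moving-image gradient, sampled later at the warped points
    mg <- lapply(1:3, function(ax) array_grad(moving$values, moving$spacing[ax], ax))
    C <- array(0, c(layouts[[1]]$m, layouts[[2]]$m, layouts[[3]]$m, 3))
    N <- prod(geom$dim)
    M <- prod(dim(C))
    step <- cfg$step_mm
    obj_log <- numeric(0)
    E_prev <- Inf
    for (it in seq_len(cfg$iterations[p])) {
      du <- vapply(1:3, function(k) as.numeric(tensor3(C[, , , k], Bx, By, Bz)), numeric(N))
      pts <- base_pts + u_prev + du
      w <- sample_at_points(moving, pts)
      r <- w - as.numeric(fx$values)
      E <- mean(r^2) + cfg$lambda * sum(C^2) / M
      obj_log <- c(obj_log, E)
      if (E > E_prev) step <- step / 2
      if (E_prev - E < cfg$tol * max(E_prev, 1e-12) && it > 2) break
      E_prev <- E
      Gc <- array(0, dim(C))
      for (k in 1:3) {
        gk <- sample_idx(mg[[k]], moving$dim, world_to_index(moving, pts),
                         "trilinear", 0)
        Gc[, , , k] <- tensor3_adjoint(array(2 * r * gk / N, geom$dim), Bx, By, Bz) +
          2 * cfg$lambda * C[, , , k] / M
      }
      gmax <- max(abs(Gc))
      if (gmax < 1e-12) break
      C <- C - (step / gmax) * Gc
    }
    passes[[p]] <- list(coefs = C, layouts = layouts)
    logs[[p]] <- obj_log
  }
  out_vals <- eval_passes(passes, grid_geometry(fixed))
  out <- displacement_field(array(out_vals, c(fixed$dim, 3)),
                            fixed$spacing, fixed$origin)
  attr(out, "objective_log") <- logs
  out
}

coarse_geometry <- function(g, spacing) {
  extent <- (g$dim - 1) * g$spacing
  dim <- pmax(2L, as.integer(floor(extent / spacing)) + 1L)
  list(origin = g$origin, spacing = spacing, dim = dim)
}

# Sum the stored per-pass B-spline fields on `geom`; n x 3 matrix of mm.
eval_passes <- function(passes, geom) {
  u <- matrix(0, prod(geom$dim), 3)
  for (ps in passes) {
    f <- bspline_field(ps$coefs, ps$layouts, geom)
    u <- u + matrix(f$values, ncol = 3)
  }
  u
}
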
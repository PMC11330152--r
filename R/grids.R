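#' Geometry-aware 3D grid containers
#'
#' `volume_grid()` represents an axis-aligned scalar field (CT in HU, dose in
#' cGy) on a regular grid: voxel centers sit at `origin + index * spacing`
#' with 0-based indices in an LPS-like world frame (mm). `binary_mask()` is the
#' same geometry with occupancy values in \{0, 1\} (ITV, PTV and their
#' propagated counterparts). `displacement_field()` stores a per-voxel 3-vector
#' displacement in mm under the fixed-frame pull-back convention: a fixed-frame
#' point `x` maps to the moving-frame point `x + u(x)`.
#'
#' @param values 3D numeric array (`volume_grid`, `binary_mask`) or 4D array
#'   with last dimension 3 (`displacement_field`). All values must be finite;
#'   mask values must be 0/1.
#' @param spacing mm 3-vector, strictly positive.
#' @param origin mm 3-vector, position of the first voxel center.
#' @param fill value returned when the grid is sampled outside its extent
#'   (0 for dose/masks, -1000 HU for CT-like images).
#' @return An object of class `volume_grid`, `binary_mask` or
#'   `displacement_field` with fields `origin`, `spacing`, `dim`, `values`.
#' @export
volume_grid <- function(values, spacing, origin = c(0, 0, 0), fill = 0) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("volume_grid values must be a 3D array")
  check_geometry(spacing, origin)
  if (!all(is.finite(values))) stop("volume_grid values must all be finite")
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dim = dim(values), values = values, fill = fill),
            class = "volume_grid")
}

#' @rdname volume_grid
#' @export
binary_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("binary_mask values must be a 3D array")
  check_geometry(spacing, origin)
  if (!all(values %in% c(0, 1))) stop("binary_mask values must be 0 or 1")
  storage.mode(values) <- "double"
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dim = dim(values), values = values, fill = 0),
            class = c("binary_mask", "volume_grid"))
}

#' @rdname volume_grid
#' @export
displacement_field <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  d <- dim(values)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement_field values must be a 4D array with last dimension 3")
  check_geometry(spacing, origin)
  if (!all(is.finite(values))) stop("displacement_field values must all be finite")
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dim = d[1:3], values = values, fill = 0),
            class = "displacement_field")
}

check_geometry <- function(spacing, origin) {
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be a strictly positive mm 3-vector")
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("origin must be a finite mm 3-vector")
  invisible(TRUE)
}

#' Rigid transform (couch correction)
#'
#' Maps a moving-frame point `z` to `R z + t`. The rotation must be orthonormal
#' within 1e-9; the default is the identity (translation-only couch shifts).
#'
#' @param translation mm 3-vector.
#' @param rotation 3x3 orthonormal matrix.
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = diag(3)) {
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation)))
    stop("translation must be a finite mm 3-vector")
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be a 3x3 orthonormal matrix (within 1e-9)")
  structure(list(translation = translation, rotation = rotation),
            class = "rigid_transform")
}

is_identity_rotation <- function(t) max(abs(t$rotation - diag(3))) < 1e-12

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<%s> %d x %d x %d, spacing %s mm, origin %s mm, range [%.4g, %.4g]\n",
              class(x)[1], x$dim[1], x$dim[2], x$dim[3],
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ","),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.displacement_field <- print.volume_grid

same_geometry <- function(a, b, tol = 1e-6) {
  all(a$dim == b$dim) && max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$spacing - b$spacing)) < tol
}

grid_geometry <- function(g) list(origin = g$origin, spacing = g$spacing, dim = g$dim)

# Voxel-center coordinates along one axis (world mm).
axis_coords <- function(g, axis) g$origin[axis] + (seq_len(g$dim[axis]) - 1) * g$spacing[axis]

# All voxel centers as an n x 3 matrix (column-major voxel order, matching
# the storage order of `values`). Memoised per geometry: the pipeline asks
# for the same 64^3 center matrix many times per fraction.
.gp_cache <- new.env(parent = emptyenv())
grid_points <- function(g) {
  key <- paste(c(g$origin, g$spacing, g$dim), collapse = "|")
  hit <- .gp_cache[[key]]
  if (!is.null(hit)) return(hit)
  cx <- axis_coords(g, 1); cy <- axis_coords(g, 2); cz <- axis_coords(g, 3)
  out <- cbind(rep(cx, times = g$dim[2] * g$dim[3]),
               rep(rep(cy, each = g$dim[1]), times = g$dim[3]),
               rep(cz, each = g$dim[1] * g$dim[2]))
  if (length(ls(.gp_cache)) > 8) rm(list = ls(.gp_cache), envir = .gp_cache)
  .gp_cache[[key]] <- out
  out
}

world_to_index <- function(g, points) {
  sweep(sweep(points, 2, g$origin, "-"), 2, g$spacing, "/")
}

#' Sample a grid at world points
#'
#' Trilinear sampling averages the 8 surrounding voxel centers; points outside
#' the grid return the grid's declared fill value (0 for masks and dose grids,
#' -1000 HU for CT-like images).
#'
#' @param grid a `volume_grid`, `binary_mask` or `displacement_field`.
#' @param points n x 3 matrix of world coordinates (mm).
#' @param mode `"trilinear"` or `"nearest"`.
#' @param fill optional override of the grid's fill value.
#' @return numeric vector of length n (`displacement_field`: n x 3 matrix).
#' @export
sample_at_points <- function(grid, points, mode = c("trilinear", "nearest"),
                             fill = NULL) {
  mode <- match.arg(mode)
  points <- matrix(as.numeric(points), ncol = 3)
  if (!all(is.finite(points))) stop("sample points must be finite world coordinates")
  if (is.null(fill)) fill <- grid$fill
  idx <- world_to_index(grid, points)
  if (inherits(grid, "displacement_field")) {
    n <- prod(grid$dim)
    out <- vapply(1:3, function(k) {
      comp <- grid$values[(k - 1) * n + seq_len(n)]
      sample_idx(comp, grid$dim, idx, mode, fill)
    }, numeric(nrow(points)))
    return(matrix(out, ncol = 3))
  }
  sample_idx(grid$values, grid$dim, idx, mode, fill)
}

sample_idx <- function(values, dim, idx, mode, fill) {
  if (mode == "trilinear") c_trilinear(as.numeric(values), as.integer(dim), idx, fill)
  else c_nearest(as.numeric(values), as.integer(dim), idx, fill)
}

#' Resample a grid onto a target geometry
#'
#' Each target voxel center is sampled from the source grid via
#' [sample_at_points()]. Binary masks are re-thresholded at 0.5 so the result
#' stays a mask. Resampling onto the identical geometry is the identity map.
#'
#' @param grid source grid.
#' @param target_geometry a grid or a `list(origin, spacing, dim)`.
#' @inheritParams sample_at_points
#' @export
resample_to <- function(grid, target_geometry, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  tg <- if (is.list(target_geometry) && !is.null(target_geometry$dim))
    target_geometry else stop("target_geometry must carry origin/spacing/dim")
  check_geometry(tg$spacing, tg$origin)
  pts <- grid_points(list(origin = tg$origin, spacing = tg$spacing, dim = tg$dim))
  vals <- sample_at_points(grid, pts, mode)
  if (inherits(grid, "binary_mask")) {
    binary_mask(array(as.numeric(vals >= 0.5), dim = tg$dim), tg$spacing, tg$origin)
  } else if (inherits(grid, "displacement_field")) {
    displacement_field(array(vals, dim = c(tg$dim, 3)), tg$spacing, tg$origin)
  } else {
    volume_grid(array(vals, dim = tg$dim), tg$spacing, tg$origin, fill = grid$fill)
  }
}

#' Mask volume in cc
#'
#' Number of occupied voxels times the voxel volume (mm^3), divided by 1000.
#' @param mask a `binary_mask`.
#' @export
mask_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values) * prod(mask$spacing) / 1000
}

#' Equivalent sphere diameter
#'
#' Diameter (mm) of the sphere with the same volume: `2 * (3 V / 4 pi)^(1/3)`
#' with `V` in mm^3.
#' @param volume_cc volume in cc (>= 0).
#' @export
equivalent_sphere_diameter_mm <- function(volume_cc) {
  if (any(volume_cc < 0)) stop("volume must be non-negative")
  2 * (3 * volume_cc * 1000 / (4 * pi))^(1 / 3)
}
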
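# Shared fixtures: tiny grids, random smooth fields, brute-force oracles.
# Everything is generated in code under fixed seeds.

tiny_geometry <- function(dim = c(8, 8, 8), spacing = c(1, 1, 1),
                          origin = c(0, 0, 0)) {
  list(origin = origin, spacing = spacing, dim = as.integer(dim))
}

# A random affine scalar field a + b.x on a grid (trilinear interpolation is
# exact for these).
random_affine_grid <- function(geom, seed) {
  set.seed(seed)
  a <- rnorm(1, 0, 10)
  b <- rnorm(3)
  co <- coord_arrays(geom)
  list(grid = volume_grid(a + b[1] * co$X + b[2] * co$Y + b[3] * co$Z,
                          geom$spacing, geom$origin),
       fun = function(p) a + as.numeric(p %*% b))
}

coord_arrays <- function(geom) {
  d <- geom$dim
  list(
    X = array(rep(geom$origin[1] + (seq_len(d[1]) - 1) * geom$spacing[1],
                  times = d[2] * d[3]), d),
    Y = array(rep(rep(geom$origin[2] + (seq_len(d[2]) - 1) * geom$spacing[2],
                      each = d[1]), times = d[3]), d),
    Z = array(rep(geom$origin[3] + (seq_len(d[3]) - 1) * geom$spacing[3],
                  each = d[1] * d[2]), d))
}

# Digital ball mask on a grid.
ball_mask <- function(geom, center, radius) {
  co <- coord_arrays(geom)
  occ <- ((co$X - center[1])^2 + (co$Y - center[2])^2 +
            (co$Z - center[3])^2) <= radius^2
  binary_mask(array(as.numeric(occ), geom$dim), geom$spacing, geom$origin)
}

# Random smooth non-folding displacement field (B-spline-like: smoothed white
# noise on a coarse control grid), peak magnitude `amp_mm`.
random_smooth_field <- function(geom, amp_mm, seed, cp_mm = 30) {
  set.seed(seed)
  lay <- actdose:::control_layout(geom, cp_mm)
  C <- array(rnorm(prod(vapply(lay, `[[`, 1L, "m")) * 3),
             c(vapply(lay, `[[`, 1L, "m"), 3))
  u <- actdose:::bspline_field(C, lay, geom)
  mx <- max(sqrt(rowSums(matrix(u$values, ncol = 3)^2)))
  displacement_field(u$values * (amp_mm / mx), geom$spacing, geom$origin)
}

# Brute-force Dx% oracle: threshold sweep over the masked doses; returns the
# interval of dose levels whose covered-fraction brackets x%.
oracle_dx_bracket <- function(doses, x_percent) {
  n <- length(doses)
  s <- sort(doses, decreasing = TRUE)
  frac <- seq_len(n) / n
  k <- which(frac >= x_percent / 100)[1]
  c(lower = if (k < n) s[k + 1] else s[n], upper = s[max(k - 1, 1)])
}

# Brute-force symmetric surface distances from voxel index sets.
oracle_surface_stats <- function(a, b) {
  pa <- actdose:::surface_points_mm(a)
  pb <- actdose:::surface_points_mm(b)
  dist1 <- apply(pa, 1, function(p) min(sqrt(colSums((t(pb) - p)^2))))
  dist2 <- apply(pb, 1, function(p) min(sqrt(colSums((t(pa) - p)^2))))
  d <- c(dist1, dist2)
  list(mean = mean(d), sd = sd(d), max = max(d))
}

# Small cohort config for pipeline tests: same physics, smaller grid.
small_cohort_config <- function(...) {
  args <- list(...)
  if (is.null(args$shape)) args$shape <- rep(48L, 3)
  if (is.null(args$spacing_mm)) args$spacing_mm <- rep(2.5, 3)
  do.call(cohort_config, args)
}

# The full fast-profile study cohort, evaluated once and cached for all
# tests that need cohort-scale results.
.cohort_cache <- new.env(parent = emptyenv())
full_cohort_run <- function() {
  if (is.null(.cohort_cache$run)) {
    cfg <- cohort_config(seed = 42)
    t0 <- Sys.time()
    ev <- evaluate_cohort(cfg)
    .cohort_cache$run <- list(
      ev = ev, config = cfg,
      runtime_min = as.numeric(Sys.time() - t0, units = "mins"))
  }
  .cohort_cache$run
}
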
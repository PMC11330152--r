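test_that("apply_rigid: identity, exact voxel shift, constants", {
  set.seed(4)
  g <- volume_grid(array(rnorm(6^3), c(6, 6, 6)), c(2, 2, 2), fill = -1000)
  expect_equal(apply_rigid(g, rigid_transform())$values, g$values)

  sh <- apply_rigid(g, rigid_transform(c(2, 0, 0)))  # one voxel along x
  expect_equal(sh$values[2:6, , ], g$values[1:5, , ])

  const <- volume_grid(array(5, c(6, 6, 6)), c(2, 2, 2), fill = 5)
  th <- pi / 7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  out <- apply_rigid(const, rigid_transform(c(1, 2, 0.5), rot))
  expect_equal(unique(as.numeric(out$values)), 5)
})

test_that("warp_image: zero field, constant-shift closed form, mask identity", {
  geom <- tiny_geometry(c(8, 8, 8), c(1.5, 1.5, 1.5))
  af <- random_affine_grid(geom, 12)
  zf <- actdose:::zero_field(geom)
  expect_equal(warp_image(af$grid, zf)$values, af$grid$values)

  u <- displacement_field(array(rep(c(1, -0.5, 2), each = prod(geom$dim)),
                                c(geom$dim, 3)), geom$spacing, geom$origin)
  w <- warp_image(af$grid, u)
  co <- coord_arrays(geom)
  inside <- co$X < 9 & co$Y > 1 & co$Z < 8.5  # sampled points stay in grid
  expected <- af$fun(cbind(as.numeric(co$X) + 1, as.numeric(co$Y) - 0.5,
                           as.numeric(co$Z) + 2))
  expect_equal(as.numeric(w$values)[inside], expected[inside], tolerance = 1e-9)

  m <- ball_mask(geom, c(5, 5, 5), 3)
  expect_equal(propagate_mask(m, zf)$values, m$values)
})

test_that("compose_rigid_dvf matches sequential application", {
  geom <- tiny_geometry(c(12, 12, 12), c(2, 2, 2))
  u <- random_smooth_field(geom, 3, seed = 8, cp_mm = 12)
  expect_equal(compose_rigid_dvf(rigid_transform(), u)$values, u$values)

  t3 <- rigid_transform(c(2.5, -1, 0.5))
  zf <- actdose:::zero_field(geom)
  vc <- compose_rigid_dvf(t3, zf)
  expect_equal(matrix(vc$values, ncol = 3),
               matrix(rep(c(2.5, -1, 0.5), each = prod(geom$dim)), ncol = 3))

  # oracle: warping through the composed field equals rigid-then-deform
  # (affine image, so both routes interpolate exactly)
  af <- random_affine_grid(geom, 15)
  v <- compose_rigid_dvf(t3, u)
  one_step <- warp_image(af$grid, v)
  moved <- apply_rigid(af$grid, rigid_transform(-t3$translation))
  two_step <- warp_image(moved, u)
  interior <- array(FALSE, c(12, 12, 12)); interior[4:9, 4:9, 4:9] <- TRUE
  expect_equal(one_step$values[interior], two_step$values[interior],
               tolerance = 1e-7)
})

test_that("invert_dvf: constants, zero field, smooth-field self consistency", {
  geom <- tiny_geometry(c(10, 10, 10), c(2, 2, 2))
  cst <- displacement_field(array(rep(c(1, 2, -1), each = 1000),
                                  c(10, 10, 10, 3)), c(2, 2, 2))
  inv <- invert_dvf(cst)
  expect_equal(matrix(inv$values, ncol = 3),
               matrix(rep(c(-1, -2, 1), each = 1000), ncol = 3),
               tolerance = 1e-6)

  zf <- actdose:::zero_field(geom)
  expect_equal(invert_dvf(zf)$values, zf$values)

  for (seed in c(2, 4, 6)) {
    u <- random_smooth_field(geom, 4, seed = seed, cp_mm = 15)
    ui <- invert_dvf(u)
    expect_lt(attr(ui, "residual_mm"), 0.05)
  }
})

test_that("log-Jacobian statistics: identity, rigid motion, uniform scaling", {
  geom <- tiny_geometry(c(10, 10, 10), c(2, 2, 2))
  m <- ball_mask(geom, c(9, 9, 9), 5)
  zf <- actdose:::zero_field(geom)
  js <- jacobian_log_stats(zf, m)
  expect_equal(unlist(js[c("min", "median", "max", "mmr", "iqr")]),
               c(min = 0, median = 0, max = 0, mmr = 0, iqr = 0))

  cst <- displacement_field(array(rep(c(3, -1, 2), each = 1000),
                                  c(10, 10, 10, 3)), c(2, 2, 2))
  jt <- jacobian_log_stats(cst, m)
  expect_equal(jt$mmr, 0, tolerance = 1e-12)
  expect_equal(jt$median, 0, tolerance = 1e-12)

  co <- coord_arrays(geom)
  scal <- displacement_field(
    array(c(0.1 * co$X, 0.1 * co$Y, 0.1 * co$Z), c(geom$dim, 3)),
    geom$spacing, geom$origin)
  jsc <- jacobian_log_stats(scal, m)
  expect_equal(jsc$median, log(1.1^3), tolerance = 1e-9)
  expect_equal(jsc$mmr, 0, tolerance = 1e-9)
})

test_that("displacement statistics over a mask", {
  geom <- tiny_geometry(c(8, 8, 8), c(1, 1, 1))
  m <- binary_mask(array(1, c(8, 8, 8)), c(1, 1, 1))
  tr <- displacement_field(array(rep(c(1, 2, 2), each = 512), c(8, 8, 8, 3)),
                           c(1, 1, 1))
  st <- displacement_stats(tr, m)
  expect_equal(unlist(st), c(min = 3, mean = 3, max = 3))

  half <- array(0, c(8, 8, 8, 3))
  half[1:4, , , 1] <- 2
  st2 <- displacement_stats(displacement_field(half, c(1, 1, 1)), m)
  expect_equal(st2$mean, 1)
  expect_equal(st2$max, 2)
  empty <- binary_mask(array(0, c(8, 8, 8)), c(1, 1, 1))
  expect_error(displacement_stats(tr, empty), "empty")
})

test_that("self-registration returns a near-zero field", {
  cfg <- small_cohort_config(seed = 2)
  pat <- generate_patient(cfg, 12)
  u <- bspline_register(pat$pct, pat$pct)
  expect_lt(mean(sqrt(rowSums(matrix(u$values, ncol = 3)^2))), 0.1)
})

test_that("known-truth recovery: 4 mm shift and 6 mm B-spline field", {
  cfg <- small_cohort_config(seed = 31, noise_sd_hu = 0)
  pat <- generate_patient(cfg, 18)
  geom <- list(origin = pat$pct$origin, spacing = pat$pct$spacing,
               dim = pat$pct$dim)
  sel <- pat$ptv$values > 0.5

  shift <- c(4, 0, 0)
  cst <- displacement_field(array(rep(shift, each = prod(geom$dim)),
                                  c(geom$dim, 3)), geom$spacing, geom$origin)
  fixed <- warp_image(pat$pct, cst)
  u_hat <- bspline_register(fixed, pat$pct)
  err <- sqrt(rowSums(sweep(matrix(u_hat$values, ncol = 3), 2, shift, "-")^2))
  expect_lt(mean(err[sel]), 0.5 * pat$pct$spacing[1])

  truth <- random_smooth_field(geom, 6, seed = 44)
  fixed2 <- warp_image(pat$pct, truth)
  u_hat2 <- bspline_register(fixed2, pat$pct)
  err2 <- sqrt(rowSums((matrix(u_hat2$values, ncol = 3) -
                          matrix(truth$values, ncol = 3))^2))
  expect_lt(mean(err2[sel]), pat$pct$spacing[1])
})

test_that("recovery error decreases with pass count", {
  cfg <- small_cohort_config(seed = 3, noise_sd_hu = 0)
  pat <- generate_patient(cfg, 45)
  geom <- list(origin = pat$pct$origin, spacing = pat$pct$spacing,
               dim = pat$pct$dim)
  sel <- pat$ptv$values > 0.5
  configs <- list(registration_config(passes = 40),
                  registration_config(passes = c(40, 20)),
                  registration_config(passes = c(40, 20, 10)))
  errs <- matrix(NA, 10, 3)
  for (s in 1:10) {
    truth <- random_smooth_field(geom, 5, seed = 600 + s)
    fixed <- warp_image(pat$pct, truth)
    for (ci in 1:3) {
      uh <- bspline_register(fixed, pat$pct, configs[[ci]])
      e <- sqrt(rowSums((matrix(uh$values, ncol = 3) -
                           matrix(truth$values, ncol = 3))^2))
      errs[s, ci] <- mean(e[sel])
    }
  }
  m <- colMeans(errs)
  expect_true(m[1] > m[2] && m[2] > m[3])
})

test_that("registration config validates pass ordering", {
  expect_error(registration_config(passes = c(10, 20)), "decreasing")
  expect_error(registration_config(passes = numeric(0)), "decreasing")
})
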
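test_that("Dx%: uniform dose, boundary limits, frozen 1..100 case", {
  geom <- tiny_geometry(c(5, 5, 4), c(1, 1, 1))
  m <- binary_mask(array(1, geom$dim), geom$spacing)
  unif <- volume_grid(array(6000, geom$dim), geom$spacing)
  expect_equal(dose_at_relative_volume(unif, m, 95), 6000)

  set.seed(8)
  d <- volume_grid(array(runif(prod(geom$dim), 0, 100), geom$dim), geom$spacing)
  expect_equal(dose_at_relative_volume(d, m, 100), min(d$values))
  expect_equal(dose_at_relative_volume(d, m, 1e-9), max(d$values))

  # 100 voxels with doses 1..100: descending-sort rank 0.95*100 = 95 -> 6.0
  # (frozen from the threshold-sweep oracle bracket [5, 7])
  g100 <- tiny_geometry(c(10, 10, 1), c(1, 1, 1))
  d100 <- volume_grid(array(sample(1:100), g100$dim), g100$spacing)
  m100 <- binary_mask(array(1, g100$dim), g100$spacing)
  expect_equal(dose_at_relative_volume(d100, m100, 95), 6)
  br <- oracle_dx_bracket(as.numeric(d100$values), 95)
  expect_gte(6, br["lower"] - 1e-12)
  expect_lte(6, br["upper"] + 1e-12)
  expect_error(dose_at_relative_volume(d100, m100, 0), "x_percent")
})

test_that("Dx% agrees with the threshold-sweep oracle on random grids", {
  for (seed in 1:6) {
    set.seed(seed)
    dims <- sample(3:9, 3, replace = TRUE)
    vals <- array(rexp(prod(dims), 1 / 5000), dims)
    occ <- array(as.numeric(runif(prod(dims)) < 0.7), dims)
    if (sum(occ) < 5) next
    d <- volume_grid(vals, c(1, 1, 1))
    m <- binary_mask(occ, c(1, 1, 1))
    for (x in c(2, 50, 95, 98)) {
      dx <- dose_at_relative_volume(d, m, x)
      br <- oracle_dx_bracket(vals[occ > 0.5], x)
      # within one interpolation step of the sweep bracket
      expect_gte(dx, br["lower"] - 1e-9)
      expect_lte(dx, br["upper"] + 1e-9)
    }
  }
})

test_that("isodose volumes: limits and analytic spherical plan", {
  geom <- tiny_geometry(c(6, 6, 6), c(2, 2, 2))
  set.seed(3)
  d <- volume_grid(array(runif(216, 1, 10), geom$dim), geom$spacing)
  expect_equal(volume_at_dose_level(d, 0), 216 * 8 / 1000)
  expect_equal(volume_at_dose_level(d, 11), 0)

  # analytic plan: uniform core + Gaussian penumbra; isodose radii known
  plan <- structure(list(prescription = 6000, n_fractions = 4,
                         isocenter = c(80, 80, 80), core_radius_mm = 15,
                         penumbra_sigma_mm = 5, scale = 1.05),
                    class = "plan_model")
  big <- tiny_geometry(c(64, 64, 64), c(2.5, 2.5, 2.5))
  rd <- plan_dose_grid(plan, big)
  r100 <- 15 + 5 * sqrt(2 * log(1.05))            # dose = prescription
  r50 <- 15 + 5 * sqrt(2 * log(2 * 1.05))         # dose = prescription / 2
  v100 <- volume_at_dose_level(rd, 6000)
  v50 <- volume_at_dose_level(rd, 3000)
  expect_equal(v100 / v50, (r100 / r50)^3, tolerance = 0.05)
})

test_that("dose statistics in masks, including subtracted-dose null case", {
  geom <- tiny_geometry(c(3, 1, 1), c(1, 1, 1))
  d <- volume_grid(array(c(2, 4, 6), geom$dim), geom$spacing)
  m <- binary_mask(array(1, geom$dim), geom$spacing)
  expect_equal(dose_stats_in_mask(d, m), list(min = 2, mean = 4, max = 6))
  sub <- volume_grid(d$values - d$values, geom$spacing)
  expect_equal(dose_stats_in_mask(sub, m), list(min = 0, mean = 0, max = 0))
  expect_error(dose_stats_in_mask(d, binary_mask(array(0, geom$dim),
                                                 geom$spacing)), "empty")
})

test_that("plan-quality indices match their closed forms", {
  expect_equal(homogeneity_index(6600, 5700, 6000), 15)
  expect_equal(homogeneity_index(5000, 5000, 6000), 0)
  expect_error(homogeneity_index(5000, 5100, 6000), "ordering")
  expect_equal(conformity_index(50, 40), 1.25)
  expect_equal(conformity_index(0, 40), 0)
  expect_error(conformity_index(10, 0), "> 0")
  expect_equal(gradient_index(40, 80), 0.5)
  expect_equal(gradient_index(30, 30), 1)
  expect_equal(gradient_measure(33.510322, 4.1887902), 10, tolerance = 1e-6)
  expect_equal(gradient_measure(12, 12), 0)
  expect_error(gradient_measure(5, 6), "v50 >= v100")
  # volume scaling by k scales GM by k^(1/3)
  expect_equal(gradient_measure(8 * 33.51, 8 * 4.1888),
               2 * gradient_measure(33.51, 4.1888), tolerance = 1e-9)
})

test_that("HI is invariant to a joint dose/prescription rescaling", {
  set.seed(9)
  d2 <- runif(5, 6000, 7000); d98 <- runif(5, 5000, 6000)
  for (i in 1:5)
    expect_equal(homogeneity_index(d2[i], d98[i], 6000),
                 homogeneity_index(3.3 * d2[i], 3.3 * d98[i], 3.3 * 6000))
})

test_that("DVH ordering holds on evaluated dose summaries", {
  geom <- tiny_geometry(c(8, 8, 8), c(2, 2, 2))
  set.seed(10)
  for (s in 1:5) {
    d <- volume_grid(array(rexp(512, 1 / 3000), geom$dim), geom$spacing)
    m <- ball_mask(geom, c(7, 7, 7), 5)
    ds <- dose_summary(d, m)
    expect_true(ds$min <= ds$d98 + 1e-9 && ds$d98 <= ds$d95 + 1e-9 &&
                  ds$d95 <= ds$d2 + 1e-9 && ds$d2 <= ds$max + 1e-9)
  }
})

test_that("volume change statistics: null cohort and pull-back scaling", {
  cases <- data.frame(patient = rep(1:3, each = 4), fraction = rep(1:4, 3),
                      itv_volume_plan_cc = 10, itv_volume_act_cc = 10,
                      ptv_volume_plan_cc = 30, ptv_volume_act_cc = 30)
  vc <- volume_change_stats(cases)
  expect_equal(vc$per_fraction$mean, rep(0, 8))
  expect_equal(vc$per_patient$mean_diff_pct, rep(0, 3))

  # uniform pull-back scaling x -> 1.1x shrinks volumes by 1/1.331
  geom <- tiny_geometry(c(40, 40, 40), c(1, 1, 1))
  big <- ball_mask(geom, c(19.5, 19.5, 19.5), 14)
  co <- coord_arrays(geom)
  ctr <- c(19.5, 19.5, 19.5)
  u <- displacement_field(array(c(0.1 * (co$X - ctr[1]), 0.1 * (co$Y - ctr[2]),
                                  0.1 * (co$Z - ctr[3])), c(geom$dim, 3)),
                          geom$spacing, geom$origin)
  shrunk <- propagate_mask(big, u)
  ratio <- mask_volume_cc(shrunk) / mask_volume_cc(big)
  expect_equal(ratio, 1 / 1.331, tolerance = 0.03)
  pct <- (ratio - 1) * 100
  expect_equal(pct, -24.9, tolerance = 1.5)
})
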
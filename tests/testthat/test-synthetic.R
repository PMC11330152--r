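test_that("patient generation is deterministic and respects lobe bookkeeping", {
  cfg <- small_cohort_config(seed = 11)
  p1 <- generate_patient(cfg, 3)
  p2 <- generate_patient(cfg, 3)
  expect_identical(p1$pct$values, p2$pct$values)
  expect_identical(p1$itv$values, p2$itv$values)
  expect_identical(p1$margin_mm, p2$margin_mm)

  lobes <- vapply(seq_len(cfg$n_patients),
                  function(i) actdose:::lobe_of_patient(cfg, i), "")
  expect_equal(as.numeric(table(lobes)[c("LUL", "LLL", "RUL", "RML", "RLL")]),
               c(21, 15, 16, 4, 16))
})

test_that("ITV is contained in PTV and the margin is a true Euclidean dilation", {
  cfg <- small_cohort_config(seed = 5, margin_mm = c(5, 5), spacing_mm = rep(2, 3),
                             shape = rep(56L, 3))
  pat <- generate_patient(cfg, 10)
  expect_true(all(pat$ptv$values[pat$itv$values > 0.5] == 1))
  expect_true(pat$margin_mm >= 5 && pat$margin_mm <= 7)

  # brute force: every PTV voxel center lies within margin of an ITV voxel
  # center, and every voxel within margin is in the PTV
  itv_idx <- which(pat$itv$values > 0.5, arr.ind = TRUE)
  ptv_idx <- which(pat$ptv$values > 0.5, arr.ind = TRUE)
  to_mm <- function(ind, g) sweep(sweep(ind - 1, 2, g$spacing, "*"), 2, g$origin, "+")
  itv_mm <- to_mm(itv_idx, pat$itv)
  ptv_mm <- to_mm(ptv_idx, pat$ptv)
  dmin <- apply(ptv_mm, 1, function(p) min(sqrt(colSums((t(itv_mm) - p)^2))))
  expect_lte(max(dmin), pat$margin_mm + 1e-9)
  all_idx <- which(pat$ptv$values > -1, arr.ind = TRUE)
  all_mm <- to_mm(all_idx, pat$ptv)
  near <- apply(all_mm, 1, function(p)
    min(sqrt(colSums((t(itv_mm) - p)^2)))) <= pat$margin_mm + 1e-9
  expect_true(all(pat$ptv$values[all_idx[near, , drop = FALSE]] == 1))
})

test_that("fractions: determinism, null scenario, and bounded smooth truth", {
  cfg <- small_cohort_config(seed = 9)
  pat <- generate_patient(cfg, 20)
  f1 <- generate_fraction(pat, cfg, 2)
  f2 <- generate_fraction(pat, cfg, 2)
  expect_identical(f1$cbct$values, f2$cbct$values)
  expect_identical(f1$setup_error$translation, f2$setup_error$translation)

  cfg0 <- small_cohort_config(seed = 9, setup_sd_mm = 0, noise_sd_hu = 0,
                              warp_amplitude_mm = c(LUL = 0, LLL = 0, RUL = 0,
                                                    RML = 0, RLL = 0))
  pat0 <- generate_patient(cfg0, 20)
  f0 <- generate_fraction(pat0, cfg0, 1)
  expect_equal(f0$cbct$values, pat0$pct$values)
  expect_equal(max(abs(f0$true_deformation$values)), 0)

  # ground truth deformations never fold at default amplitudes
  fr <- generate_fraction(pat, cfg, 1)
  J <- actdose:::jacobian_determinant(fr$true_deformation)
  expect_gt(min(J), 0)
})

test_that("pure-translation scenario shifts the ITV centroid by the translation", {
  cfg <- small_cohort_config(seed = 21)
  pat <- generate_patient(cfg, 30)
  geom <- list(origin = pat$pct$origin, spacing = pat$pct$spacing,
               dim = pat$pct$dim)
  shift <- c(4, -2, 6)  # integer multiples of the 2.5 mm spacing not required
  v <- displacement_field(array(rep(shift, each = prod(geom$dim)),
                                c(geom$dim, 3)), geom$spacing, geom$origin)
  moved <- propagate_mask(pat$itv, v)
  centroid <- function(m) {
    idx <- which(m$values > 0.5, arr.ind = TRUE)
    colMeans(sweep(sweep(idx - 1, 2, m$spacing, "*"), 2, m$origin, "+"))
  }
  expect_equal(centroid(moved), centroid(pat$itv) - shift,
               tolerance = 0.4, ignore_attr = TRUE)
})

test_that("lower-lobe phantoms move more than upper-lobe phantoms", {
  cfg <- small_cohort_config(seed = 33)
  mean_disp <- function(pid, n_seeds) {
    pat <- generate_patient(cfg, pid)
    mean(vapply(seq_len(n_seeds), function(s) {
      fr <- generate_fraction(pat, cfg, 1, fraction_seed = 5000 + s)
      displacement_stats(fr$true_deformation, pat$ptv)$mean
    }, 0))
  }
  upper <- c(mean_disp(1, 16), mean_disp(40, 16))    # LUL, RUL
  lower <- c(mean_disp(25, 16), mean_disp(60, 16))   # LLL, RLL
  expect_gt(mean(lower), mean(upper))
})

test_that("reference plan: D95 normalization, linearity, penumbra tail", {
  cfg <- small_cohort_config(seed = 13)
  pat <- generate_patient(cfg, 8)
  plan <- generate_plan(pat, cfg)
  geom <- list(origin = pat$pct$origin, spacing = pat$pct$spacing,
               dim = pat$pct$dim)
  rd <- plan_dose_grid(plan, geom)
  expect_equal(dose_at_relative_volume(rd, pat$ptv, 95), 6000, tolerance = 0.1)

  fr_dose <- compute_fraction_dose(plan, geom)
  expect_equal(fr_dose$values * 4, rd$values)

  far <- pat$isocenter + c(plan$core_radius_mm + 5 * plan$penumbra_sigma_mm + 1,
                           0, 0)
  expect_lt(sample_at_points(rd, rbind(far)), 0.01 * plan$prescription)
  expect_error(generate_plan(list(ptv = binary_mask(array(0, c(4, 4, 4)),
                                                    c(1, 1, 1))), cfg),
               "empty PTV")
})

test_that("margin outside the configured range is rejected", {
  expect_error(cohort_config(margin_mm = c(4, 7)), "margin")
  expect_error(cohort_config(margin_mm = 8), "margin")
  expect_error(cohort_config(lobe_counts = c(LUL = 20, LLL = 20, RUL = 20,
                                             RML = 10, RLL = 10)), "sum")
})

test_that("regression tables: determinism and noiseless identifiability", {
  rc <- regression_table_config(seed = 77, sigma_eps = 0)
  t1 <- generate_regression_table(rc)
  t2 <- generate_regression_table(rc)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 288)

  fit <- suppressWarnings(  # lm warns on the perfect noiseless fit
    ols_fit(t1, "d95", c("dHI", "dmean_pct", "dsc", "warp_mean")))
  expect_equal(fit$coefficients$b, c(-21.49, 33.45, 558.55, -33.71),
               tolerance = 1e-9)
  expect_equal(fit$intercept$b, 2032.97, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("copula option induces the requested covariate correlation", {
  R <- diag(4)
  R[1, 4] <- R[4, 1] <- 0.6
  rc <- regression_table_config(n_cases = 4000, seed = 5, copula_corr = R,
                                sigma_eps = 50)
  tab <- generate_regression_table(rc)
  expect_gt(cor(tab$dHI, tab$warp_mean), 0.4)
  fit <- ols_fit(tab, "d95", c("dHI", "warp_mean"))
  expect_gt(fit$coefficients$vif[1], 1.2)
})
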
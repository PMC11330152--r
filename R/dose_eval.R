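#' Build the adaptive CT
#'
#' `ACT(x) = PCT(total_map(x))` where the total fixed-to-moving map composes
#' the rigid couch correction and the deformable field
#' ([compose_rigid_dvf()]). The ACT represents the patient at treatment time
#' on the CBCT (fixed) frame.
#'
#' @param pct planning CT (`volume_grid`).
#' @param setup rigid setup transform.
#' @param dvf deformable field on the fixed grid.
#' @export
make_act <- function(pct, setup, dvf) {
  warp_image(pct, compose_rigid_dvf(setup, dvf))
}

#' Propagate a structure through a total map
#'
#' Occupancy is interpolated trilinearly through the pull-back map and
#' thresholded at 0.5, yielding the adaptive structure (aRS) on the fixed
#' grid. An empty result raises a warning (structure left the field of view).
#'
#' @param mask_on_pct structure on the planning frame.
#' @param total_map `displacement_field` of the total fixed-to-moving map.
#' @export
propagate_mask <- function(mask_on_pct, total_map) {
  stopifnot(inherits(mask_on_pct, "binary_mask"),
            inherits(total_map, "displacement_field"))
  pts <- grid_points(total_map) + matrix(total_map$values, ncol = 3)
  occ <- sample_at_points(mask_on_pct, pts)
  out <- binary_mask(array(as.numeric(occ >= 0.5), total_map$dim),
                     total_map$spacing, total_map$origin)
  if (sum(out$values) == 0) warning("propagated structure is empty")
  out
}

#' Per-fraction delivered dose on the fixed frame
#'
#' The plan's dose cloud stays fixed to the plan isocenter in room
#' coordinates; any residual setup error displaces the anatomy relative to
#' it. The analytic plan dose is evaluated on the fixed geometry and divided
#' by the number of fractions.
#'
#' @param plan a `plan_model`.
#' @param fixed_geometry geometry of the CBCT/ACT frame.
#' @param setup residual rigid setup error (kept for the interface; the dose
#'   cloud itself does not move with the patient).
#' @export
compute_fraction_dose <- function(plan, fixed_geometry, setup = rigid_transform()) {
  rd <- plan_dose_grid(plan, fixed_geometry)
  volume_grid(rd$values / plan$n_fractions, rd$spacing, rd$origin, fill = 0)
}

#' Warp a fixed-frame dose back to the planning frame
#'
#' `dose_on_pct(y) = ard_fixed(y + v_inv(y))` with `v_inv` the inverse of the
#' total map ([invert_dvf()]), so each planning-frame tissue element reads
#' the dose at its treatment-time position. Dose is interpolated as a point
#' quantity (no Jacobian weighting).
#'
#' @param ard_fixed per-fraction dose on the fixed frame.
#' @param dvf_total_inverse inverse displacement field on the planning frame.
#' @export
warp_dose_to_pct <- function(ard_fixed, dvf_total_inverse) {
  warp_image(ard_fixed, dvf_total_inverse)
}

#' Average warped-back fraction doses
#'
#' Voxelwise arithmetic mean of the (total-course-scaled) per-fraction doses
#' in the planning frame. Counts other than 4 are allowed (generalized mean)
#' but flagged with a message.
#'
#' @param doses_on_pct list of `volume_grid`s on identical geometries.
#' @export
accumulate_mean <- function(doses_on_pct) {
  stopifnot(length(doses_on_pct) >= 1)
  g1 <- doses_on_pct[[1]]
  for (g in doses_on_pct[-1])
    if (!same_geometry(g1, g)) stop("accumulation requires identical geometries")
  if (length(doses_on_pct) != 4)
    message(sprintf("accumulating %d fraction doses (expected 4)", length(doses_on_pct)))
  acc <- Reduce(`+`, lapply(doses_on_pct, `[[`, "values")) / length(doses_on_pct)
  volume_grid(acc, g1$spacing, g1$origin, fill = 0)
}

#' Evaluate one patient end to end
#'
#' For each fraction: rigid-align the planning CT with the recorded couch
#' correction, register it deformably onto the CBCT, compose the total map,
#' build the ACT, propagate the ITV/PTV, compute the per-fraction dose, invert
#' the total map and warp the dose back to the planning frame; finally average
#' the four total-course-scaled doses. One case record per fraction collects
#' the geometric QA (DSC, surface distances, Warp and log-Jacobian statistics
#' over the PTV) and the dosimetric parameters (planned/delivered/subtracted
#' dose statistics, D2/D95/D98, V100/V50, HI/ΔHI/CI/GI/GM).
#'
#' @param patient a `phantom_patient`.
#' @param plan its `plan_model`.
#' @param fractions list of `fraction_scenario`s.
#' @param reg_cfg a [registration_config()].
#' @param keep_volumes keep per-fraction grids (`act`, doses, fields) in the
#'   result; off by default to bound memory over a cohort.
#' @return list with `cases` (one data.frame row per fraction), `delivered`
#'   (accumulated total-course dose on the planning frame), `planned`
#'   (plan dose on the planning frame), `patient_summary`, and `fractions`
#'   (per-fraction QA, plus grids when `keep_volumes`).
#' @export
evaluate_patient <- function(patient, plan, fractions,
                             reg_cfg = registration_config(),
                             keep_volumes = FALSE) {
  stopifnot(inherits(patient, "phantom_patient"), inherits(plan, "plan_model"))
  geom <- grid_geometry(patient$pct)
  planned_rd <- plan_dose_grid(plan, geom)
  plan_itv <- dose_summary(planned_rd, patient$itv)
  plan_ptv <- dose_summary(planned_rd, patient$ptv)
  hi_plan <- homogeneity_index(plan_ptv$d2, plan_ptv$d98, plan$prescription)

  # the plan dose cloud is static in room coordinates, so the per-fraction
  # dose grid is identical for every fraction
  ard <- compute_fraction_dose(plan, geom)
  ard_total <- volume_grid(ard$values * plan$n_fractions, ard$spacing,
                           ard$origin, fill = 0)
  v100 <- volume_at_dose_level(ard_total, plan$prescription)
  v50 <- volume_at_dose_level(ard_total, 0.5 * plan$prescription)
  rows <- list()
  fr_out <- list()
  doses_on_pct <- list()
  for (fs in fractions) {
    # couch correction recorded by CBCT matching: moves the PCT content by
    # -t so that pct_rigid(x) = pct(x + t)
    t_setup <- fs$setup_error$translation
    pct_rigid <- apply_rigid(patient$pct, rigid_transform(-t_setup))
    u_hat <- bspline_register(fs$cbct, pct_rigid, reg_cfg)
    v <- compose_rigid_dvf(fs$setup_error, u_hat)
    act <- warp_image(patient$pct, v)
    ars_itv <- propagate_mask(patient$itv, v)
    ars_ptv <- propagate_mask(patient$ptv, v)
    empty <- sum(ars_ptv$values) == 0 || sum(ars_itv$values) == 0

    ptv_rigid <- propagate_mask(patient$ptv, compose_rigid_dvf(
      fs$setup_error, zero_field(geom)))
    warp_st <- displacement_stats(u_hat, ptv_rigid)
    jac_st <- jacobian_log_stats(u_hat, ptv_rigid)
    dsc <- dice(ptv_rigid, ars_ptv)
    surf <- if (!empty) surface_distance_stats(ptv_rigid, ars_ptv)
    else list(mean = NA_real_, sd = NA_real_, max = NA_real_)

    v_inv <- invert_dvf(v)
    ard_on_pct <- warp_dose_to_pct(ard, v_inv)
    doses_on_pct[[length(doses_on_pct) + 1]] <-
      volume_grid(ard_on_pct$values * plan$n_fractions, ard_on_pct$spacing,
                  ard_on_pct$origin, fill = 0)

    del_itv <- if (!empty) dose_summary(ard_total, ars_itv) else NULL
    del_ptv <- if (!empty) dose_summary(ard_total, ars_ptv) else NULL
    sub_total <- volume_grid(doses_on_pct[[length(doses_on_pct)]]$values -
                               planned_rd$values, geom$spacing, geom$origin)
    sub_ptv <- dose_stats_in_mask(sub_total, patient$ptv)
    sub_itv <- dose_stats_in_mask(sub_total, patient$itv)

    hi_del <- if (!empty) homogeneity_index(del_ptv$d2, del_ptv$d98,
                                            plan$prescription) else NA_real_

    rows[[length(rows) + 1]] <- data.frame(
      patient = patient$patient_id, fraction = fs$fraction_index,
      lobe = patient$lobe, excluded = empty,
      itv_volume_plan_cc = plan_itv$volume_cc,
      itv_volume_act_cc = if (empty) NA_real_ else del_itv$volume_cc,
      ptv_volume_plan_cc = plan_ptv$volume_cc,
      ptv_volume_act_cc = if (empty) NA_real_ else del_ptv$volume_cc,
      itv_eq_sphere_mm = plan_itv$eq_sphere_mm,
      ptv_eq_sphere_mm = plan_ptv$eq_sphere_mm,
      plan_itv_min = plan_itv$min, plan_itv_mean = plan_itv$mean,
      plan_itv_max = plan_itv$max,
      plan_ptv_min = plan_ptv$min, plan_ptv_mean = plan_ptv$mean,
      plan_ptv_max = plan_ptv$max, plan_ptv_d2 = plan_ptv$d2,
      plan_ptv_d95 = plan_ptv$d95, plan_ptv_d98 = plan_ptv$d98,
      del_itv_min = null_na(del_itv, "min"), del_itv_mean = null_na(del_itv, "mean"),
      del_itv_max = null_na(del_itv, "max"),
      del_ptv_min = null_na(del_ptv, "min"), del_ptv_mean = null_na(del_ptv, "mean"),
      del_ptv_max = null_na(del_ptv, "max"), del_ptv_d2 = null_na(del_ptv, "d2"),
      del_ptv_d95 = null_na(del_ptv, "d95"), del_ptv_d98 = null_na(del_ptv, "d98"),
      dmean_pct = null_na(del_ptv, "mean") / plan$prescription * 100,
      sub_ptv_min = sub_ptv$min, sub_ptv_mean = sub_ptv$mean,
      sub_ptv_max = sub_ptv$max,
      sub_itv_min = sub_itv$min, sub_itv_mean = sub_itv$mean,
      sub_itv_max = sub_itv$max,
      v100_cc = v100, v50_cc = v50,
      dsc = dsc, surf_mean = surf$mean, surf_sd = surf$sd, surf_max = surf$max,
      warp_min = warp_st$min, warp_mean = warp_st$mean, warp_max = warp_st$max,
      logjac_min = jac_st$min, logjac_q1 = jac_st$q1,
      logjac_median = jac_st$median, logjac_q3 = jac_st$q3,
      logjac_max = jac_st$max, logjac_mmr = jac_st$mmr, logjac_iqr = jac_st$iqr,
      hi_plan = hi_plan, hi_del = hi_del, dHI = hi_del - hi_plan,
      ci = conformity_index(v100, plan_ptv$volume_cc),
      gi = gradient_index(v100, v50),
      gm_mm = gradient_measure(v50, v100),
      stringsAsFactors = FALSE)

    fr <- list(fraction_index = fs$fraction_index, qa = list(
      warp = warp_st, jacobian = jac_st, dsc = dsc, surface = surf),
      inversion_residual_mm = attr(v_inv, "residual_mm"))
    if (keep_volumes)
      fr <- c(fr, list(act = act, ars_itv = ars_itv, ars_ptv = ars_ptv,
                       ard_fixed = ard, ard_on_pct = ard_on_pct,
                       dvf = v, dvf_inverse = v_inv))
    fr_out[[length(fr_out) + 1]] <- fr
  }
  delivered <- accumulate_mean(doses_on_pct)
  patient_summary <- list(
    planned_itv = plan_itv, planned_ptv = plan_ptv,
    delivered_itv = dose_summary(delivered, patient$itv),
    delivered_ptv = dose_summary(delivered, patient$ptv),
    max_abs_diff_cGy = max(abs(delivered$values - planned_rd$values)))
  list(cases = do.call(rbind, rows), delivered = delivered,
       planned = planned_rd, patient_summary = patient_summary,
       fractions = fr_out)
}

null_na <- function(x, field) if (is.null(x)) NA_real_ else x[[field]]

zero_field <- function(geom) {
  displacement_field(array(0, c(geom$dim, 3)), geom$spacing, geom$origin)
}
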
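#' Dose at a relative volume (Dx%)
#'
#' The dose level received by at least `x`% of the structure volume: masked
#' voxel doses are sorted descending and linearly interpolated at rank
#' `x/100 * N` (clamped to `[1, N]`). `D100%` is the minimum masked dose; the
#' `x -> 0` limit is the maximum.
#'
#' @param dose a `volume_grid` of dose (cGy).
#' @param mask a non-empty `binary_mask` on the same geometry.
#' @param x_percent relative volume in `(0, 100]`.
#' @export
dose_at_relative_volume <- function(dose, mask, x_percent) {
  stopifnot(inherits(dose, "volume_grid"), inherits(mask, "binary_mask"))
  if (!same_geometry(dose, mask)) stop("dose and mask geometries differ")
  if (x_percent <= 0 || x_percent > 100) stop("x_percent must be in (0, 100]")
  d <- dose$values[mask$values > 0.5]
  if (!length(d)) stop("empty mask")
  d <- sort(d, decreasing = TRUE)
  r <- min(max(x_percent / 100 * length(d), 1), length(d))
  lo <- floor(r)
  hi <- ceiling(r)
  d[lo] + (r - lo) * (d[hi] - d[lo])
}

#' Absolute volume above an isodose level
#'
#' Total volume (cc) of the whole dose grid, not restricted to any structure,
#' with dose at or above `level_cGy` (the V100%/V50% isodose volumes when
#' `level` is 100%/50% of the prescription).
#'
#' @param dose a `volume_grid` of dose (cGy).
#' @param level_cGy isodose level, >= 0.
#' @export
volume_at_dose_level <- function(dose, level_cGy) {
  stopifnot(inherits(dose, "volume_grid"))
  if (level_cGy < 0) stop("level must be >= 0")
  sum(dose$values >= level_cGy) * prod(dose$spacing) / 1000
}

#' Dose statistics within a structure
#'
#' Exact voxelwise minimum, mean and maximum over the masked voxels.
#' @inheritParams dose_at_relative_volume
#' @export
dose_stats_in_mask <- function(dose, mask) {
  stopifnot(inherits(dose, "volume_grid"), inherits(mask, "binary_mask"))
  if (!same_geometry(dose, mask)) stop("dose and mask geometries differ")
  d <- dose$values[mask$values > 0.5]
  if (!length(d)) stop("empty mask")
  list(min = min(d), mean = mean(d), max = max(d))
}

#' Homogeneity index
#'
#' `HI = (D2% - D98%) * 100 / D_prescribed`; 0 for a uniform dose. ΔHI is the
#' delivered-minus-planned HI difference.
#'
#' @param d2,d98 near-maximum and near-minimum doses (cGy), `d2 >= d98`.
#' @param d_prescribed prescription (cGy), > 0.
#' @export
homogeneity_index <- function(d2, d98, d_prescribed) {
  if (d_prescribed <= 0) stop("prescription must be > 0")
  if (d2 < d98 - 1e-9) stop("d2 < d98 violates DVH ordering")
  (d2 - d98) * 100 / d_prescribed
}

#' Conformity index
#'
#' `CI = V100% / structure volume`.
#' @param v100_cc volume of the 100% isodose (cc).
#' @param structure_volume_cc structure volume (cc), > 0.
#' @export
conformity_index <- function(v100_cc, structure_volume_cc) {
  if (structure_volume_cc <= 0) stop("structure volume must be > 0")
  v100_cc / structure_volume_cc
}

#' Gradient index
#'
#' `GI = V100% / V50%`, at most 1 for nested isodose volumes (the 50% isodose
#' encloses the 100% isodose).
#' @param v100_cc,v50_cc isodose volumes (cc), `v50_cc > 0`.
#' @export
gradient_index <- function(v100_cc, v50_cc) {
  if (v50_cc <= 0) stop("V50% must be > 0")
  v100_cc / v50_cc
}

#' Gradient measure
#'
#' Difference of the equivalent-sphere radii of the 50% and 100% isodose
#' volumes, in mm: `(3 V50 / 4 pi)^(1/3) - (3 V100 / 4 pi)^(1/3)` with
#' volumes in mm^3.
#' @param v50_cc,v100_cc isodose volumes (cc), `v50_cc >= v100_cc >= 0`.
#' @export
gradient_measure <- function(v50_cc, v100_cc) {
  if (v100_cc < 0 || v50_cc < v100_cc) stop("requires v50 >= v100 >= 0")
  (3 * v50_cc * 1000 / (4 * pi))^(1 / 3) - (3 * v100_cc * 1000 / (4 * pi))^(1 / 3)
}

#' Full dose summary of a structure
#'
#' Convenience wrapper returning the DVH row of the case table: min/mean/max,
#' D2%, D95%, D98% (cGy), structure volume (cc) and equivalent-sphere
#' diameter (mm).
#'
#' @inheritParams dose_at_relative_volume
#' @export
dose_summary <- function(dose, mask) {
  st <- dose_stats_in_mask(dose, mask)
  vol <- mask_volume_cc(mask)
  list(min = st$min, mean = st$mean, max = st$max,
       d2 = dose_at_relative_volume(dose, mask, 2),
       d95 = dose_at_relative_volume(dose, mask, 95),
       d98 = dose_at_relative_volume(dose, mask, 98),
       volume_cc = vol,
       eq_sphere_mm = equivalent_sphere_diameter_mm(vol))
}

#' Target volume change across the treatment course
#'
#' Percent volume difference of the propagated (adaptive) structures relative
#' to the planning volume, `(V_ACT - V_PCT) / V_PCT * 100`, summarized as
#' mean and SD per fraction index for the ITV and the PTV, plus the
#' per-patient average difference against the planning ITV volume.
#'
#' @param cases case table carrying `patient`, `fraction`,
#'   `itv_volume_plan_cc`, `itv_volume_act_cc`, `ptv_volume_plan_cc`,
#'   `ptv_volume_act_cc`.
#' @return list with `per_fraction` (structure, fraction, mean, sd, n) and
#'   `per_patient` (patient, itv_volume_plan_cc, mean_diff_pct).
#' @export
volume_change_stats <- function(cases) {
  need <- c("patient", "fraction", "itv_volume_plan_cc", "itv_volume_act_cc",
            "ptv_volume_plan_cc", "ptv_volume_act_cc")
  if (!all(need %in% names(cases))) stop("case table lacks volume columns")
  if (any(cases$itv_volume_plan_cc <= 0) || any(cases$ptv_volume_plan_cc <= 0))
    stop("zero planning volume")
  pct <- function(act, plan) (act - plan) / plan * 100
  cases$itv_diff <- pct(cases$itv_volume_act_cc, cases$itv_volume_plan_cc)
  cases$ptv_diff <- pct(cases$ptv_volume_act_cc, cases$ptv_volume_plan_cc)
  per_fraction <- do.call(rbind, lapply(c("itv", "ptv"), function(s) {
    v <- cases[[paste0(s, "_diff")]]
    agg <- aggregate(v, by = list(fraction = cases$fraction),
                     FUN = function(z) c(mean = mean(z), sd = sd(z), n = length(z)))
    data.frame(structure = toupper(s), fraction = agg$fraction,
               mean = agg$x[, "mean"], sd = agg$x[, "sd"], n = agg$x[, "n"])
  }))
  pp <- aggregate(cases$itv_diff, by = list(patient = cases$patient), FUN = mean)
  vol <- aggregate(cases$itv_volume_plan_cc, by = list(patient = cases$patient),
                   FUN = function(z) z[1])
  per_patient <- data.frame(patient = pp$patient, itv_volume_plan_cc = vol$x,
                            mean_diff_pct = pp$x)
  list(per_fraction = per_fraction, per_patient = per_patient)
}
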
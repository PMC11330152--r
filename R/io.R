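#' Read and write volumes as NIfTI
#'
#' Scalar grids are stored as 3D NIfTI, displacement fields as 4D NIfTI with
#' three components and the vector intent code. Only axis-aligned affines are
#' supported; geometry (origin/spacing) and values round-trip exactly at
#' float64 precision. Masks are written as their 0/1 values and recognized on
#' read.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param as `"auto"` infers mask/vector/scalar; or force `"volume"`,
#'   `"mask"`, `"dvf"`.
#' @export
read_volume <- function(path, as = c("auto", "volume", "mask", "dvf")) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  if (max(abs(xf[1:3, 1:3] - diag(diag(xf[1:3, 1:3])))) > 1e-6)
    stop("oblique orientations are not supported")
  spacing <- abs(diag(xf[1:3, 1:3]))
  origin <- xf[1:3, 4]
  vals <- as.array(img)
  d <- dim(vals)
  is_vec <- length(d) == 4 && d[4] == 3
  if (as == "dvf" || (as == "auto" && is_vec))
    return(displacement_field(array(as.numeric(vals), d), spacing, origin))
  if (length(d) == 4 && d[4] == 1) { vals <- array(vals, d[1:3]); d <- d[1:3] }
  if (length(d) != 3) stop("expected a 3D scalar or 3-component 4D volume")
  if (as == "mask" || (as == "auto" && all(vals %in% c(0, 1))))
    return(binary_mask(array(as.numeric(vals), d), spacing, origin))
  volume_grid(array(as.numeric(vals), d), spacing, origin,
              fill = if (min(vals) <= -500) -1000 else 0)
}

#' @rdname read_volume
#' @param obj a `volume_grid`, `binary_mask` or `displacement_field`.
#' @export
write_volume <- function(obj, path) {
  stopifnot(inherits(obj, "volume_grid") || inherits(obj, "displacement_field"))
  vals <- obj$values
  if (inherits(obj, "binary_mask")) storage.mode(vals) <- "double"
  img <- RNifti::asNifti(vals)
  pd <- if (length(dim(vals)) == 4) c(obj$spacing, 1) else obj$spacing
  img <- RNifti::`pixdim<-`(img, pd)
  aff <- rbind(cbind(diag(obj$spacing), obj$origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Serialize and restore a cohort configuration
#'
#' JSON round-trip of [cohort_config()] for reproducible runs.
#' @param config a `cohort_config`.
#' @param path JSON file path.
#' @export
write_cohort_config <- function(config, path) {
  x <- unclass(config)
  # named atomic vectors become JSON objects so their names survive the trip
  for (f in c("lobe_counts", "warp_amplitude_mm")) x[[f]] <- as.list(x[[f]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("lobe_counts", "warp_amplitude_mm")) x[[f]] <- unlist(x[[f]])
  do.call(cohort_config, x[setdiff(names(x), "profile")])
}

# FNV-1a hash of a serialized R object, as a hex string; stamps outputs so a
# re-run with the same config + seed is recognizably identical.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Evaluate a synthetic cohort
#'
#' Generates every patient, plan and fraction from the cohort configuration
#' and runs [evaluate_patient()] on each, returning the stacked case table
#' (one row per patient-fraction) and per-patient dose summaries. Cases whose
#' propagated structure came out empty are flagged in the `excluded` column.
#'
#' @param config a [cohort_config()].
#' @param reg_cfg a [registration_config()].
#' @param patients subset of patient ids (default all).
#' @param progress print one line per patient.
#' @export
evaluate_cohort <- function(config, reg_cfg = registration_config(),
                            patients = NULL, progress = FALSE) {
  if (is.null(patients)) patients <- seq_len(config$n_patients)
  case_list <- vector("list", length(patients))
  summaries <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    pid <- patients[i]
    pat <- generate_patient(config, pid)
    plan <- generate_plan(pat, config)
    frs <- lapply(seq_len(config$fractions_per_patient), function(f)
      generate_fraction(pat, config, f))
    ev <- evaluate_patient(pat, plan, frs, reg_cfg)
    case_list[[i]] <- ev$cases
    summaries[[i]] <- c(list(patient = pid, lobe = pat$lobe), ev$patient_summary)
    if (progress)
      message(sprintf("patient %3d/%d (%s): delivered ITV Dmin %.0f cGy",
                      pid, length(patients), pat$lobe,
                      ev$patient_summary$delivered_itv$min))
  }
  list(cases = do.call(rbind, case_list), patients = summaries,
       config = config)
}

#' Analyse a case table
#'
#' The statistics layer over a case table (from [evaluate_cohort()] or
#' [generate_regression_table()]): stepwise multiple linear regression of PTV
#' D95% on the candidate parameters with tolerance/VIF diagnostics, one-way
#' ANOVA of D95%, DSC and Warp_mean by lung lobe, the high-ΔHI subgroup
#' refit, and studentized-residual outlier flagging.
#'
#' @param cases case table; flagged (`excluded`) rows are dropped first.
#' @param dependent response column (default `del_ptv_d95`, falling back to
#'   `d95` for tabular cohorts).
#' @param candidates candidate predictors for the stepwise selection.
#' @param p_enter,p_remove stepwise thresholds (SPSS defaults).
#' @param subgroup_threshold,subgroup_variable high-HI exclusion rule for the
#'   refit (default ΔHI <= 17).
#' @param outlier_sd studentized-residual cutoff.
#' @export
analyze_cases <- function(cases, dependent = NULL,
                          candidates = c("dHI", "dmean_pct", "dsc", "warp_mean"),
                          p_enter = 0.05, p_remove = 0.10,
                          subgroup_threshold = 17, subgroup_variable = "dHI",
                          outlier_sd = 3) {
  if ("excluded" %in% names(cases)) cases <- cases[!cases$excluded, , drop = FALSE]
  if (is.null(dependent))
    dependent <- if ("del_ptv_d95" %in% names(cases)) "del_ptv_d95" else "d95"
  model <- stepwise_mlr(cases, dependent, candidates, p_enter, p_remove)
  outliers <- flag_outliers(model, cases, outlier_sd)
  sub <- filter_subgroup(cases, subgroup_threshold, subgroup_variable)
  sub_model <- stepwise_mlr(sub, dependent, candidates, p_enter, p_remove)
  anovas <- list()
  for (v in intersect(c(dependent, "dsc", "warp_mean"), names(cases)))
    anovas[[v]] <- oneway_anova(cases, "lobe", v)
  vol <- if (all(c("itv_volume_plan_cc", "itv_volume_act_cc") %in% names(cases)))
    volume_change_stats(cases) else NULL
  list(model = model, subgroup_model = sub_model,
       n_subgroup_excluded = attr(sub, "n_excluded"),
       anova = anovas, outliers = outliers, volume_change = vol)
}

#' Run the full pipeline and write its artifacts
#'
#' Simulate, evaluate and analyse a cohort, writing `cases.csv`,
#' `analysis.json`, `qa_report.json` and `report.md` (plus `cohort.json`)
#' under `out_dir`. Deterministic given the configuration (which carries the
#' seed); every artifact embeds the config hash and seed.
#'
#' @inheritParams evaluate_cohort
#' @param out_dir output directory (created if needed).
#' @param ... passed to [analyze_cases()].
#' @export
run_pipeline <- function(config, reg_cfg = registration_config(),
                         out_dir = "results", patients = NULL,
                         progress = FALSE, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(config_hash = config_hash(list(config, reg_cfg)),
                seed = config$seed)
  write_cohort_config(config, file.path(out_dir, "cohort.json"))
  ev <- evaluate_cohort(config, reg_cfg, patients, progress)
  cases <- ev$cases
  cases$config_hash <- stamp$config_hash
  cases$seed <- stamp$seed
  write.csv(cases, file.path(out_dir, "cases.csv"), row.names = FALSE)
  an <- analyze_cases(ev$cases, ...)
  jsonlite::write_json(list(
    stamp = stamp,
    model = regression_json(an$model),
    subgroup_model = regression_json(an$subgroup_model),
    n_subgroup_excluded = an$n_subgroup_excluded,
    anova = lapply(an$anova, function(a)
      list(groups = a$groups, f = a$f, p = a$p)),
    n_outliers = length(an$outliers$flagged)),
    file.path(out_dir, "analysis.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  qa_cols <- intersect(c("dsc", "surf_mean", "surf_max", "warp_mean",
                         "warp_max", "logjac_mmr", "logjac_iqr"), names(cases))
  qa <- c(stamp, lapply(cases[qa_cols], function(v)
    list(mean = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE),
         max = max(v, na.rm = TRUE))))
  jsonlite::write_json(qa, file.path(out_dir, "qa_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(pipeline_report(ev, an, stamp), file.path(out_dir, "report.md"))
  invisible(list(evaluation = ev, analysis = an, stamp = stamp,
                 out_dir = out_dir))
}

regression_json <- function(m) {
  list(terms = m$coefficients,
       intercept = m$intercept, r2 = m$r2, adj_r2 = m$adj_r2, n = m$n)
}

pipeline_report <- function(ev, an, stamp) {
  cases <- ev$cases[!ev$cases$excluded, ]
  c(sprintf("# Delivered-dose evaluation report (config %s, seed %d)",
            stamp$config_hash, stamp$seed),
    "",
    sprintf("Cases evaluated: %d (%d excluded).", nrow(ev$cases),
            sum(ev$cases$excluded)),
    sprintf("Delivered PTV D95%%: mean %.1f cGy (SD %.1f).",
            mean(cases$del_ptv_d95), sd(cases$del_ptv_d95)),
    sprintf("PTV DSC: mean %.3f; Warp_mean: mean %.2f mm.",
            mean(cases$dsc), mean(cases$warp_mean)),
    sprintf("Stepwise model retained: %s (adjusted R2 %.3f).",
            paste(an$model$coefficients$term, collapse = ", "), an$model$adj_r2),
    sprintf("Subgroup refit retained: %s (%d cases excluded).",
            paste(an$subgroup_model$coefficients$term, collapse = ", "),
            an$n_subgroup_excluded),
    sprintf("Outliers flagged: %d.", length(an$outliers$flagged)))
}
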
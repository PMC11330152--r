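#!/usr/bin/env Rscript
# Step 1 — define the study cohort and inspect one phantom.
#
# Fixes the cohort conditions (72 patients, 4 fractions each, 5-7 mm margin,
# 6000 cGy to 95% of the PTV, lobe-dependent motion), writes them to
# results/cohort.json, and exports one example phantom (planning CT, ITV,
# PTV, one ground-truth deformation and CBCT) as NIfTI for inspection.

library(actdose)

cfg <- cohort_config(seed = 42)
dir.create("results/volumes", showWarnings = FALSE, recursive = TRUE)
write_cohort_config(cfg, "results/cohort.json")

cat("Cohort:", cfg$n_patients, "patients x", cfg$fractions_per_patient,
    "fractions =", cfg$n_patients * cfg$fractions_per_patient, "ACT cases\n")
cat("Grid:", paste(cfg$shape, collapse = "x"), "voxels at",
    paste(cfg$spacing_mm, collapse = "x"), "mm\n")
print(default_lobe_summary()[, c("lobe", "n_patients", "warp_mean_mm")])

pat <- generate_patient(cfg, 1)
plan <- generate_plan(pat, cfg)
fr <- generate_fraction(pat, cfg, 1)
cat(sprintf("\nExample patient 1 (%s): ITV %.1f cc, PTV %.1f cc, margin %.1f mm\n",
            pat$lobe, mask_volume_cc(pat$itv), mask_volume_cc(pat$ptv),
            pat$margin_mm))
cat(sprintf("Plan: core radius %.1f mm, planned PTV D95%% = %.1f cGy\n",
            plan$core_radius_mm,
            dose_at_relative_volume(plan_dose_grid(plan, pat$pct), pat$ptv, 95)))
cat(sprintf("Fraction 1: setup error (%.2f, %.2f, %.2f) mm, mean PTV warp %.2f mm\n",
            fr$setup_error$translation[1], fr$setup_error$translation[2],
            fr$setup_error$translation[3],
            displacement_stats(fr$true_deformation, pat$ptv)$mean))

write_volume(pat$pct, "results/volumes/patient01_pct.nii.gz")
write_volume(pat$itv, "results/volumes/patient01_itv.nii.gz")
write_volume(pat$ptv, "results/volumes/patient01_ptv.nii.gz")
write_volume(fr$cbct, "results/volumes/patient01_fx1_cbct.nii.gz")
write_volume(fr$true_deformation, "results/volumes/patient01_fx1_truth_dvf.nii.gz")
cat("\nWrote results/cohort.json and example volumes under results/volumes/\n")
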
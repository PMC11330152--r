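#!/usr/bin/env Rscript
# Step 3 — planned-vs-delivered dose comparison and target volume change.
#
# Summarizes, per structure, the planned and delivered dose statistics over
# the cohort (the delivered dose to the ITV should stay close to the plan
# even where PTV coverage degrades), and the per-fraction percent volume
# difference of the propagated ITV/PTV against the planning volumes.

library(actdose)

cases <- read.csv("results/cases.csv")
cases <- cases[!cases$excluded, ]

summarize <- function(cols, label) {
  out <- data.frame(metric = sub("^(plan|del)_", "", cols),
                    mean = vapply(cols, function(c) mean(cases[[c]]), 0),
                    sd = vapply(cols, function(c) sd(cases[[c]]), 0))
  cat("\n", label, "\n", sep = "")
  print(out, row.names = FALSE, digits = 5)
  out
}

plan_ptv <- summarize(c("plan_ptv_min", "plan_ptv_mean", "plan_ptv_max",
                        "plan_ptv_d95"), "Planned dose to PTV [cGy]")
del_ptv <- summarize(c("del_ptv_min", "del_ptv_mean", "del_ptv_max",
                       "del_ptv_d95"), "Delivered dose to PTV [cGy]")
plan_itv <- summarize(c("plan_itv_min", "plan_itv_mean", "plan_itv_max"),
                      "Planned dose to ITV [cGy]")
del_itv <- summarize(c("del_itv_min", "del_itv_mean", "del_itv_max"),
                     "Delivered dose to ITV [cGy]")

rel <- 100 * (del_itv$mean - plan_itv$mean) / plan_itv$mean
cat(sprintf("\nITV delivered-vs-planned relative difference: %s %%\n",
            paste(sprintf("%.2f", rel), collapse = ", ")))

vc <- volume_change_stats(cases)
cat("\nPercent volume difference of propagated structures vs plan:\n")
print(vc$per_fraction, row.names = FALSE, digits = 3)

dir.create("results", showWarnings = FALSE)
write.csv(rbind(cbind(structure = "PTV", frame = "plan", plan_ptv),
                cbind(structure = "PTV", frame = "delivered", del_ptv),
                cbind(structure = "ITV", frame = "plan", plan_itv),
                cbind(structure = "ITV", frame = "delivered", del_itv)),
          "results/dose_summary.csv", row.names = FALSE)
write.csv(vc$per_fraction, "results/volume_change.csv", row.names = FALSE)
cat("\nWrote results/dose_summary.csv and results/volume_change.csv\n")
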
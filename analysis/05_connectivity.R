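#!/usr/bin/env Rscript
# Resting-state functional connectivity: per-subject 7x7 matrices, infant and
# adult group means, aggregate-subject significance, and the infant-vs-adult
# per-cell comparison.  Infants from both ages are combined after checking
# that no cell differs between 5 and 8 weeks, mirroring the study design.
# ROIs are the ground-truth regions of the generating scene (synthetic mode).
# Requires 01_simulate_cohort.R.

suppressPackageStartupMessages(library(boldflow))

manifest <- read.csv("results/cohort_manifest.csv")
cfg <- read_config("results/pipeline_config.yaml")
scene <- scene_spec()
rois <- setNames(lapply(ROI_ORDER, function(l) scene_roi(scene, l)), ROI_ORDER)

runs <- lapply(manifest$rest_nii, read_bold_nifti)
groups <- manifest$group

# 5w vs 8w: no cell should differ, licensing the combined infant group
infants <- groups %in% c("5w", "8w")
check <- run_rest_pipeline(runs[infants], rois, groups[groups %in% c("5w", "8w")],
                           config = cfg)
min_p <- min(check$comparison$p[upper.tri(check$comparison$p)], na.rm = TRUE)
cat(sprintf("5w vs 8w connectivity: smallest per-cell p = %.3f%s\n", min_p,
            if (min_p > 0.05) " -> groups combined" else " (inspect before combining)"))

groups2 <- ifelse(infants, "infant", "adult")
res <- run_rest_pipeline(runs, rois, groups2, config = cfg)

for (g in c("infant", "adult")) {
  write_connectivity_csv(res$group_means[[g]],
                         sprintf("results/connectivity_mean_%s.csv", g))
  agg <- res$aggregate[[g]]
  write.csv(round(agg$p, 6), sprintf("results/connectivity_aggp_%s.csv", g))
}
write.csv(round(res$comparison$p, 6), "results/connectivity_group_p.csv")
write.csv(res$comparison$flags, "results/connectivity_group_flags.csv")

cat(sprintf("\ninfant group mean (n = %d):\n", sum(infants)))
print(round(unclass(res$group_means$infant), 2))
cat(sprintf("\nadult group mean (n = %d):\n", sum(!infants)))
print(round(unclass(res$group_means$adult), 2))
cat("\ncells differing between infants and adults (upper triangle):\n")
flags <- res$comparison$flags
sig <- which(flags != "", arr.ind = TRUE)
if (nrow(sig)) {
  for (k in seq_len(nrow(sig))) {
    cat(sprintf("  %s - %s: p = %.4f %s\n",
                ROI_ORDER[sig[k, 1]], ROI_ORDER[sig[k, 2]],
                res$comparison$p[sig[k, 1], sig[k, 2]], flags[sig[k, 1], sig[k, 2]]))
  }
} else cat("  none\n")
cat("\nmatrices in results/connectivity_*.csv\n")
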
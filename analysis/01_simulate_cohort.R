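#!/usr/bin/env Rscript
# Simulate the study cohort: two infant groups (5 and 8 weeks) with
# block-design series (coherent-vs-blank, coherent-vs-random) and a
# resting-state series per subject, plus an adult comparison group for the
# connectivity analysis.  Volumes are written as NIfTI under scratch/cohort/
# (large, regenerable), motion traces as 6-column text, ground truth as YAML
# sidecars; the cohort manifest goes to results/.
#
# Group structure mirrors the study: the 8-week scene carries the stronger
# V6 and V1 responses and a faster hemodynamic response (the 5-week scene
# adds a 0.5 s delay), while MT+ and PIVC amplitudes are shared - the
# developmental pattern the downstream comparisons should recover.

suppressPackageStartupMessages(library(boldflow))

out_dir <- "scratch/cohort"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)
set.seed(20260927)

sched <- make_condition_schedule(tr_s = 3, block_s = 21, n_periods = 6,
                                 n_dummy = 4)

scene_8w <- scene_spec()           # default amplitudes (MT .6, V6 .5, PIVC -.3, V1 .2)
rois_5w <- default_rois()
for (i in seq_along(rois_5w)) {
  lab <- rois_5w[[i]]$label
  if (startsWith(lab, "V6")) rois_5w[[i]]$amp_c1c2 <- 0.23   # immature V6
  if (lab == "V1") rois_5w[[i]]$amp_blank <- 0.25            # weaker V1 response
  rois_5w[[i]]$delay_s <- 0.5                                # slower hemodynamics
}
scene_5w <- scene_spec(rois = rois_5w)

# resting-state target correlations (scene ROI order:
# MT+L, MT+R, V6L, V6R, PIVCL, PIVCR, V1): strong interhemispheric homotopic
# connectivity in all groups; V1 couplings weakly positive in infants,
# negative for MT+/PIVC in adults
make_target <- function(v1_mt, v1_pivc) {
  m <- diag(7)
  set_pair <- function(i, j, r) m[i, j] <<- m[j, i] <<- r
  set_pair(1, 2, 0.70)               # MT+ L-R
  set_pair(3, 4, 0.60)               # V6 L-R
  set_pair(5, 6, 0.55)               # PIVC L-R
  for (j in 3:4) set_pair(7, j, 0.40)     # V1 - V6
  for (j in 1:2) set_pair(7, j, v1_mt)    # V1 - MT+
  for (j in 5:6) set_pair(7, j, v1_pivc)  # V1 - PIVC
  stopifnot(isSymmetric(m),
            min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) > 0)
  m
}
target_infant <- make_target(v1_mt = 0.15, v1_pivc = 0.10)
target_adult  <- make_target(v1_mt = -0.20, v1_pivc = -0.20)

cohort <- rbind(
  data.frame(subject = sprintf("5w_%d", 1:8), group = "5w"),
  data.frame(subject = sprintf("8w_%d", 1:9), group = "8w"),
  data.frame(subject = sprintf("A_%d", 1:8), group = "adult")
)

manifest <- list()
for (i in seq_len(nrow(cohort))) {
  id <- cohort$subject[i]
  grp <- cohort$group[i]
  scene <- if (grp == "5w") scene_5w else scene_8w
  target <- if (grp == "adult") target_adult else target_infant
  seed <- 1000L * i

  paths <- list(subject = id, group = grp)
  if (grp != "adult") {                       # infants: two stimulus series
    for (contrast in c("stim_vs_blank", "c1_vs_c2")) {
      sim <- simulate_block_run(scene, sched, contrast, seed = seed +
                                  (contrast == "c1_vs_c2"))
      tag <- if (contrast == "c1_vs_c2") "random" else "blank"
      nii <- file.path(out_dir, sprintf("%s_%s.nii.gz", id, tag))
      write_bold_nifti(sim$run, nii)
      write_motion_trace(sim$motion, sub("\\.nii\\.gz$", ".par", nii))
      write_ground_truth(sim$truth, sub("\\.nii\\.gz$", "_truth.yaml", nii))
      paths[[paste0(tag, "_nii")]] <- nii
    }
  }
  rest <- simulate_rest_run(scene, target, n_timepoints = 124, seed = seed + 7L)
  nii <- file.path(out_dir, sprintf("%s_rest.nii.gz", id))
  write_bold_nifti(rest$run, nii)
  write_ground_truth(rest$truth, sub("\\.nii\\.gz$", "_truth.yaml", nii))
  trace <- simulate_motion_trace(124, drift_sd = 0.008,
                                 spike_rate = if (grp == "5w") 0.5 else 1,
                                 seed = seed + 9L)
  write_motion_trace(trace, file.path(out_dir, sprintf("%s_rest.par", id)))
  paths$rest_nii <- nii
  manifest[[i]] <- as.data.frame(paths, check.names = FALSE)
}
manifest <- do.call(rbind, lapply(manifest, function(m) {
  for (col in c("blank_nii", "random_nii")) if (is.null(m[[col]])) m[[col]] <- NA
  m[, c("subject", "group", "blank_nii", "random_nii", "rest_nii")]
}))
write.csv(manifest, "results/cohort_manifest.csv", row.names = FALSE)
write_config(default_config(), "results/pipeline_config.yaml")

cat(sprintf("simulated %d subjects (%s)\n", nrow(manifest),
            paste(sprintf("%s: %d", names(table(cohort$group)),
                          table(cohort$group)), collapse = ", ")))
cat("volumes + traces under", out_dir, "; manifest in results/cohort_manifest.csv\n")
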
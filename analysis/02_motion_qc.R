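#!/usr/bin/env Rscript
# Motion quality control over the simulated cohort: framewise displacement,
# suprathreshold counts and the per-group / per-series summary table, plus
# the screening verdict for every series.  Requires 01_simulate_cohort.R.

suppressPackageStartupMessages(library(boldflow))

manifest <- read.csv("results/cohort_manifest.csv")
cfg <- read_config("results/pipeline_config.yaml")

traces <- list(); group <- c(); series <- c()
screen_rows <- list()
for (i in seq_len(nrow(manifest))) {
  row <- manifest[i, ]
  files <- c(blank = row$blank_nii, random = row$random_nii, rest = row$rest_nii)
  for (s in names(files)) {
    if (is.na(files[[s]])) next
    tr <- read_motion_trace(sub("\\.nii\\.gz$", ".par", files[[s]]))
    traces[[length(traces) + 1]] <- tr
    group <- c(group, row$group)
    series <- c(series, s)
    scr <- screen_run(tr, cfg$translation_limit_mm, cfg$rotation_limit_mm,
                      cfg$head_radius_mm, cfg$seg_fd_mm, cfg$min_segment)
    fd <- framewise_displacement(tr, cfg$head_radius_mm)
    screen_rows[[length(screen_rows) + 1]] <- data.frame(
      subject = row$subject, group = row$group, series = s,
      verdict = scr$verdict, n_intervals = nrow(scr$intervals),
      fd_mean = mean(fd$fd),
      n_supra = count_suprathreshold(fd, cfg$fd_threshold_mm))
  }
}

summary_tab <- summarize_motion(traces, group, series,
                                fd_threshold_mm = cfg$fd_threshold_mm,
                                radius_mm = cfg$head_radius_mm)
write.csv(summary_tab, "results/motion_summary.csv", row.names = FALSE)
screen_tab <- do.call(rbind, screen_rows)
write.csv(screen_tab, "results/motion_screening.csv", row.names = FALSE)

cat("motion summary (one row per group x series):\n")
print(summary_tab[, c("group", "series", "n_traces", "fd_mean", "fd_sd",
                      "n_supra_mean")], digits = 2)
cat(sprintf("\nverdicts: %s\n",
            paste(sprintf("%s: %d", names(table(screen_tab$verdict)),
                          table(screen_tab$verdict)), collapse = ", ")))
cat("tables in results/motion_summary.csv, results/motion_screening.csv\n")
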
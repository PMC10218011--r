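#!/usr/bin/env Rscript
# Between-group (5 vs 8 weeks) comparisons of the ROI response measures:
# two-tailed t tests on amplitude, circular-statistics comparison on phase,
# per area (hemispheres pooled).  Requires 03_stimulus_pipeline.R.

suppressPackageStartupMessages(library(boldflow))

stats <- read.csv("results/roi_stats.csv")
stats <- stats[stats$label %in% ROI_ORDER, ]
stats$area <- sub(" [LR]$", "", stats$label)

rows <- list()
for (area in unique(stats$area)) {
  sub <- stats[stats$area == area, ]
  a5 <- sub[sub$group == "5w", ]
  a8 <- sub[sub$group == "8w", ]
  if (nrow(a5) < 2 || nrow(a8) < 2) next
  amp <- compare_groups(a5$amplitude_pct, a8$amplitude_pct, "amplitude")
  ph5 <- a5$phase_deg[!is.na(a5$phase_deg)]
  ph8 <- a8$phase_deg[!is.na(a8$phase_deg)]
  ph <- compare_groups(ph5, ph8, "phase")
  rows[[length(rows) + 1]] <- data.frame(
    area = area,
    amp_5w = amp$mean[1], amp_5w_sd = amp$sd[1],
    amp_8w = amp$mean[2], amp_8w_sd = amp$sd[2],
    amp_p = amp$p,
    phase_5w = ph$mean[1], phase_5w_sd = ph$sd[1],
    phase_8w = ph$mean[2], phase_8w_sd = ph$sd[2],
    phase_p = ph$p)
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/group_comparisons.csv", row.names = FALSE)

cat("5-week vs 8-week comparisons (hemispheres pooled):\n\n")
for (i in seq_len(nrow(tab))) {
  r <- tab[i, ]
  cat(sprintf("%-5s amplitude %.2f +/- %.2f vs %.2f +/- %.2f %%  (p = %.3g)\n",
              r$area, r$amp_5w, r$amp_5w_sd, r$amp_8w, r$amp_8w_sd, r$amp_p))
  cat(sprintf("      phase     %.0f +/- %.0f vs %.0f +/- %.0f deg (p = %.3g)\n",
              r$phase_5w, r$phase_5w_sd, r$phase_8w, r$phase_8w_sd, r$phase_p))
}
cat("\ntable in results/group_comparisons.csv\n")
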
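# boldflow

Analysis pipeline for periodic block-design fMRI and resting-state
functional connectivity in motion-sensitive visual cortex (bilateral MT+,
V6, PIVC, and V1), built for the low-SNR, motion-prone regime of infant
imaging where every stage has to be explicit about what it discards.

The pipeline chains:

* **Motion QC** — framewise displacement
  `FD(t) = |Δdx| + |Δdy| + |Δdz| + |Δα| + |Δβ| + |Δγ|`
  (rotations as arc length at a 50 mm head radius), suprathreshold counts at
  0.5 mm, and series exclusion (>4 mm translation / 5 mm rotation range) or
  segmentation into still intervals.
* **GLM** — voxelwise OLS with a gamma-HRF-convolved condition boxcar
  (1 = C1, 0 = C2, so the weight is the C1−C2 response in percent signal
  change), six motion regressors and a two-cycle GLM-Fourier high-pass.
  The HRF dispersion is calibrated so the model response to the 21 s/21 s
  paradigm has a fundamental phase of exactly 64°.
* **Seed & mask** — V1 seed (p ≤ 0.01 in the stimulus-vs-blank map inside a
  calcarine prior), seed correlation maps at lags 0 and 3 s (one TR), and
  their union (p ≤ 0.05) as the analysis mask.
* **ROI spectral statistics** — sign-coherent focus labeling inside the mask
  (p ≤ 0.05), percent time courses, period averages over good periods, the
  TR 3–6 windowed mean, and the FFT statistic
  `SNR = |A(f₀)| / RMS(|A(f₀−1)|, |A(f₀+1)|)` with phase in degrees and
  circular (vector-resultant) group statistics.
* **Connectivity** — 7×7 ROI-pair Pearson matrices
  (1 = MT R, 2 = MT L, 3 = V1, 4 = V6 R, 5 = V6 L, 6 = PIVC R, 7 = PIVC L),
  group means, aggregate-subject significance (z-score, concatenate,
  correlate: equal-length aggregate r = mean per-subject r), and per-cell
  two-tailed t tests on Fisher-z correlations.

A synthetic generator reproduces the acquisition structure (88-point task
runs with 4 dummies at TR 3 s, 124-point rest runs, 3 mm voxels,
AR(1)+drift noise, motion spikes, imposed rest correlations) with full
ground truth, so every stage is testable end to end. See
`vignettes/methods.Rmd` for the model, parameter and design rationale.

## Worked example

Simulate one subject's two stimulus series and run the full pipeline:

```r
library(boldflow)

scene <- scene_spec()                      # 7 ROIs, ground truth known
sched <- make_condition_schedule()         # TR 3 s, 21 s blocks, 6 periods
blank  <- simulate_block_run(scene, sched, "stim_vs_blank", seed = 11)
random <- simulate_block_run(scene, sched, "c1_vs_c2",      seed = 12)

res <- run_stimulus_pipeline(
  list(run = blank$run,  motion = blank$motion),
  list(run = random$run, motion = random$motion),
  scene)
res$roi_stats[, c("label", "n", "amplitude_pct", "snr", "phase_deg")]
```

prints (seed-exact):

```
       label   n amplitude_pct       snr phase_deg
1      MT+ R  34    0.62517540 17.441644  63.39218
2       V6 L  31    0.49909481 25.896502  61.96155
3       V6 R  30    0.49172962 31.050559  63.14021
4      MT+ L  29    0.57642124 17.877230  64.18092
5 unassigned 142    0.02396365  1.826296  47.47924
6     PIVC L  23   -0.27140523  9.439312 242.99044
7     PIVC R  30   -0.33160029 22.648661 247.51212
8         V1  36    0.19576391  6.387837  65.64353
```

Reading it: recovered amplitudes sit near the programmed 0.6 / 0.5 / −0.3 /
0.2 % (PIVC negative — it responds more to random than to coherent motion);
SNR is the fundamental-to-neighbour-bin amplitude ratio (values ≫ 1 are
reliable responses); phases cluster near the canonical 64° for positive
areas and near 64° + 180° for the sign-inverted PIVC. The `unassigned` row
pools the scattered suprathreshold noise voxels that match no prior region —
its near-zero amplitude and SNR ≈ 1 mark it as spurious activity.

The numbered scripts under `analysis/` run the same machinery over a
simulated two-age-group cohort plus adults — `01_simulate_cohort.R`,
`02_motion_qc.R`, `03_stimulus_pipeline.R`, `04_group_comparisons.R`,
`05_connectivity.R` — writing their tables under `results/`. For example,
script 05 flags exactly the V1–MT+ and V1–PIVC cells as the infant-vs-adult
connectivity differences built into the cohort.

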
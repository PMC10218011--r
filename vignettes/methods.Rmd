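---
title: "Methods: block-design BOLD responses and resting connectivity in motion-sensitive cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: block-design BOLD responses and resting connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldflow)
```

# Scope

`boldflow` implements the analysis chain used to measure visual-motion
responses and resting-state connectivity in a small, fixed set of cortical
areas — bilateral MT+, V6 and PIVC plus primary visual cortex (V1) — from
periodic block-design fMRI at TR 3 s.  The chain is:

1. motion quality control by framewise displacement (FD), with series
   exclusion and segmentation;
2. a voxelwise ordinary-least-squares GLM with a gamma-HRF-convolved
   condition regressor, six motion nuisance regressors and a two-cycle
   GLM-Fourier high-pass;
3. V1-seed detection from the stimulus-vs-blank contrast, lag-0 and
   lag-one-TR seed correlation maps, and their union as an analysis mask;
4. ROI labeling of the coherent-vs-random contrast inside the mask,
   percent-signal-change time courses, period averaging, a windowed mean
   response, and a spectral SNR/phase statistic with circular group
   statistics;
5. 7x7 ROI-pair resting-state correlation matrices, group means,
   aggregate-subject significance, and per-cell two-tailed group
   comparisons.

A synthetic-data generator reproduces the acquisition structure so the whole
chain is testable without scanner data.  The package is organised as an
analysis workflow: the numbered scripts under `analysis/` are thin narrative
drivers over the exported functions, writing their tables under `results/`.

# The paradigm and its model

Stimulus runs alternate two conditions (C1, C2) in equal 21 s blocks, six
periods of 42 s per run, preceded by four dummy scans: 88 volumes acquired,
84 retained.  Resting runs have 124 volumes (120 retained).  The condition
regressor is a boxcar (1 during C1, 0 during C2) convolved with a
gamma-variate HRF; with this coding the GLM weight on the regressor is
directly the C1 minus C2 response.  Dummy volumes carry a decaying signal
transient in the generator, so the dummy-discard convention is exercised
rather than assumed.

## HRF parameterisation: the 64-degree anchor

The HRF is a gamma density with shape $a$ and dispersion $b$ (seconds),
integrated over TR bins so the discrete kernel has exactly unit mass.  No
parameter pair is hand-picked: with the shape fixed at 3, the dispersion is
solved numerically so that the fundamental-frequency phase of the convolved
21 s / 21 s boxcar, relative to the boxcar itself, is exactly 64 degrees —
the value a canonical hemodynamic model produces for this paradigm and the
single analytic anchor the pipeline is validated against.  The solved
default is $b \approx 3.20$ s (time-to-peak $\approx 6.4$ s, a plausible
value for infant hemodynamics).

```{r hrf}
h <- default_hrf()
h
sched <- make_condition_schedule()
box <- boxcar_regressor(sched)
fundamental_phase(convolve_hrf(box, h), sched$n_periods, box)
```

Phase convention: phases are reported in degrees in [0, 360) relative to C1
onset, with the sign fixed so that a *later* response has a *larger* phase
(delaying a series by one TR adds $360 \cdot 6 / 84 \approx 25.7$ degrees).
An area responding more strongly to C2 than C1 (PIVC) appears 180 degrees
away, near 244 degrees.

# Motion quality control

FD sums the absolute frame-to-frame deltas of the three translations (mm)
and the three rotations converted from degrees to arc length at a 50 mm head
radius (about the distance from head center to occipital cortex in infants).
FD at the first time point is undefined and stored as 0.  Time points with
FD > 0.5 mm are counted per series.

Screening distinguishes three outcomes.  A run whose cumulative per-axis
displacement range exceeds 4 mm (translation) or 5 mm of rotation arc with
no usable still span is excluded.  When heavy movement (FD > 1 mm) and
stillness are copresent, the run is segmented: the retained intervals are
the maximal quiet spans of at least 28 time points — two full stimulus
periods, the minimum for which period averaging remains possible — whose
within-span ranges stay inside the limits.  Sporadic moderate FD events
(0.5–1 mm) are counted but do not by themselves cut a run, so that series with a handful of suprathreshold points are retained, as QC practice expects.
The exclusion norm (range per axis) and the segmentation trigger are
documented choices, configurable in `default_config()`; neither is uniquely
determined by the procedure itself.

# The GLM

The design matrix holds the convolved condition regressor, six demeaned
motion regressors, sine/cosine pairs at 1 and 2 cycles per run (the
GLM-Fourier high-pass) and a constant: 12 columns for 84 retained points.
Fitting is OLS per voxel with no prewhitening, matching classical practice
for this design; with AR(1) noise this inflates nominal significance,
which the null-calibration tests quantify on white noise rather than hide.
t statistics use df = rows − rank; the Z-equivalent score is the
standard-normal quantile of the t tail probability, computed on the log
scale so large statistics do not overflow.

Betas are rescaled to percent signal change using the fitted constant column
as the voxel baseline rather than the voxel temporal mean: the temporal mean
contains the response term itself, so mean-scaling would bias a noiseless
0.5 % amplitude by a factor $1/(1 + 0.5\bar r/100)$, while intercept scaling
recovers it exactly — this exactness is asserted at machine precision in the
tests.  Noiseless voxels (zero residual variance) are flagged with p = 0
when they carry an effect and p = 1 when flat, instead of failing on a zero
division.

# Seed, lagged correlation maps, and the union mask

V1-seed: voxels with p <= 0.01 and positive response in the
stimulus-vs-blank map, intersected with a calcarine prior region; the
largest connected component(s) (6-neighbour adjacency; ties all kept) form
the seed.  The seed time course is then correlated with every voxel at lags
0 and 3 s (one TR), after two-cycle high-passing of both series; p values
use the r-to-t transform with partial-correlation degrees of freedom
(overlap − 2 − number of high-pass regressors), which keeps the null
calibration exact.  The analysis mask is the union of the voxels significant
(p <= 0.05) at either lag.

The mask admits **both correlation signs** by default.  A positive-only mask
was considered and is available (`mask_sign = "pos"`), but PIVC responds
*negatively* under visual stimulation, so its task-driven signal is
anticorrelated with the V1 seed; a positive-only mask would exclude PIVC
from an analysis whose purpose includes PIVC, while the admission of
negative correlations is exactly what makes the observed masks contain it.

ROI labeling inside the mask uses the coherent-vs-random map at p <= 0.05.
Because foci are sign-coherent (positive or negative responses), connected
components are computed separately for the two signs.  Each component is
assigned to the nearest prior region center (within 4 voxels); components
matching no prior are reported as "unassigned".  When several components
share a label, the focus kept is the largest — smaller same-label
satellites are almost always suprathreshold noise and would dilute the ROI
time course (including them biased recovered amplitudes by ~13 %; with the
largest-focus rule the bias is below 10 %, most of it residual
cluster-boundary bleed).  In synthetic mode the priors are the generator's
ground-truth centers; with real data a prior-region file plays the role of
the anatomist.  V1 itself is carried forward from the seed stage rather
than relabeled.  No multiple-comparison correction is applied inside the
mask — a faithful-reproduction choice, not a statistical recommendation.

# ROI response measures

Time courses are the spatial mean over ROI voxels, converted to percent of
the ROI temporal mean.  A stimulus period (14 TRs) is "good" iff it lies
entirely inside one retained interval; partial periods contribute to
nothing.  The per-TR mean and SD across good periods form the period
average; the windowed mean response averages TRs 3–6 inclusive (9–18 s
after C1 onset).

The spectral summary concatenates the good periods in order — keeping the
fundamental on an exact Fourier bin; zero-filling the gaps was rejected
because it leaks power across bins — and takes the DFT.  SNR is the
fundamental amplitude divided by the RMS amplitude of the two adjacent
bins; under white noise all three bins share one noise law, so the null SNR
is near 1 (null median about 0.91, verified against an independent
three-bin simulation).  Significance is a one-sided F(2, 4) test of the
fundamental power against the mean neighbour-bin power (each bin power is a
scaled chi-square with 2 df under Gaussian noise); the test is a documented
reconstruction — significance markers for this statistic are conventionally
reported without naming a test — and it is calibrated (4.8 % rejections at the 5 % level in the null
suite).  At least two good periods are required, otherwise the neighbour
bins do not exist inside the signal band.  Half periods are not used
spectrally; they would place the fundamental off-bin.

Group statistics on phase use vector computation: the circular mean is the
angle of the resultant, and the circular SD is the RMS of wrapped angular
deviations from it.  The mean may be unweighted (default) or SNR-weighted;
both are available because the vector formulation admits either reading.
Group comparisons are two-tailed t tests: directly on amplitudes (pooled
variance), and for phases on wrapped angular deviations — each group is
centered on its own circular mean and the wrapped difference of the two
circular means is tested against the pooled within-group angular dispersion
(a small-dispersion linearisation that remains stable under wraparound,
e.g. for groups straddling 0 degrees).

# Resting-state connectivity

Per subject, the seven ROI mean time courses (dummies dropped, two-cycle
high-pass) are Pearson-correlated into a symmetric 7x7 matrix in the fixed
order 1 = MT R, 2 = MT L, 3 = V1, 4 = V6 R, 5 = V6 L, 6 = PIVC R,
7 = PIVC L.  Subjects lacking an ROI get NA rows and are excluded pairwise.
Group matrices are elementwise means.  Significance comes from the
aggregate subject: each subject's ROI series is z-scored and concatenated;
for equal-length runs the aggregate correlation *equals* the mean of the
per-subject correlations (an algebraic identity of z-scored concatenation,
asserted to 1e-6 in the tests), and its r-to-t transform with
df = total points − 2 supplies each cell's p.  Between-group comparisons
are per-cell two-tailed t tests on Fisher-z-transformed correlations
(variance stabilisation; a raw-r mode is also available), flagged at 0.05 and 0.01 on the upper triangle.

# The synthetic generator

The generator emulates the acquisition rather than the brain: a 24x24x12
grid of 3 mm voxels with seven disjoint spherical ROIs (spheres, unlike the
irregular clusters of real data — the shape affects no tested statistic),
baseline 1000 a.u., and percent amplitudes defaulting to the 0.2–0.8 %
band observed for these areas: for coherent-vs-random, MT+ 0.6, V6 0.5,
PIVC −0.3, V1 0.2; for stimulus-vs-blank, MT+ 0.3, V6 0.25, PIVC −0.2,
V1 0.5.  PIVC is negative in both contrasts, reproducing its
stronger-to-random, negative-to-stimulation behaviour.  A per-ROI
hemodynamic delay is applied as a circular Fourier shift of the convolved
regressor, adding exactly $\mathrm{delay} \times 360 / 42$ degrees of
fundamental phase — which is what makes injected delays exactly recoverable.

Noise is white Gaussian (default SD 0.2 % of baseline), AR(1)-filtered
(coefficient 0.3, scaled to preserve the stationary SD), plus slow drift.
Drift is modeled as random-phase fluctuations at 1 and 2 cycles per run
(default SD ~0.5 %): the band scanner drift occupies and precisely what the
two-cycle GLM-Fourier high-pass is designed to remove, so the high-pass
stage has something real to do and removes it exactly.  A linear-ramp drift
was rejected: a ramp leaks power into the 6-cycle stimulus bin that no
two-cycle high-pass can absorb, which is a statement about the mismatch of
that noise model with this preprocessing rather than about the pipeline.

Resting runs draw latent ROI signals with an imposed correlation matrix
(via its symmetric PSD square root; non-PSD targets are rejected) at 1 %
of baseline, on top of the same voxel noise.  Averaging an ROI of $m$
voxels attenuates observed inter-ROI correlations by
$\sqrt{a_i a_j}$ with $a = s^2 / (s^2 + \sigma^2 / m)$; the factors and the
attenuated target are returned in the ground truth so recovery tests can
correct for them instead of absorbing the attenuation into a loosened
tolerance.  Motion traces are cumulative small Gaussian wander plus
step-like spikes (one translation axis jumps and stays), so each spike
produces exactly one suprathreshold FD event and ground-truth spike counts
are directly comparable with QC counts.

What the generator does *not* emulate: spatial autocorrelation of noise,
physiological (cardiac/respiratory) rhythms, sleep-state changes, image
artifacts, partial-volume effects, or any interaction between the motion
trace and the images (runs are generated aligned; motion enters the
analysis only through the parameter files, as the screening and nuisance
stages require).  Passing tests therefore validate the statistical chain
under its own assumptions, not robustness to real-scanner artifacts.

# Numerical choices and degenerate inputs

* Schedules reject block durations that are not TR multiples.
* Constant voxels in correlation maps get r = 0, p = 1; constant ROI series
  are excluded from the aggregate subject with a warning.
* Constant motion regressors are dropped with a warning; any remaining rank
  deficiency is an error naming the collinear columns.
* A zero circular resultant leaves the circular mean undefined (flagged).
* Component labeling uses 6-neighbour (face) adjacency; ties for the
  largest seed component keep all tied components.
* The rest series nominally spans "124 time points"; at TR 3 s that is
  6 min 12 s of data, and the generator uses exactly 124 x 3 s.

# Problem sizes used by the validation suite

The test and acceptance suites run on one CPU with deliberately scaled
problem sizes, chosen as the smallest that leave Monte-Carlo error well
inside each tolerance: null calibrations use 20 replicates of 1000 voxels;
full-pipeline amplitude recovery uses 50 replicates of the default scene
(bias < 10 % of the true amplitude per area); injected-delay recovery uses
10 replicates (mean phase error < 5 degrees); connectivity recovery uses 50
replicates at 120 retained points, and the group-difference power check 50
replicates of a 13-vs-8-subject cohort on a reduced grid with single-voxel
ROIs, compared against the analytic noncentral-t power on the Fisher-z
scale.

# Known limitations

* OLS without prewhitening means AR(1) noise inflates voxelwise
  significance; thresholds here reproduce the classical uncorrected procedure
  and should not be read as calibrated error rates on autocorrelated data.
* The spectral significance test and the Z-equivalent score are
  reconstructions of conventions usually reported without full specification, documented as such.
* Labeling assigns components to the *nearest* prior center; with real
  anatomy a neuroradiologist performed this step, and the distance rule is
  only a stand-in.
* The phase group comparison assumes concentrated (small-dispersion) phase
  distributions; for nearly uniform phases a rank or randomisation test
  would be preferable.
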
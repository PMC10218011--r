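# shared fixtures: small scenes and runs built in code

# default study scene (24 x 24 x 12, seven ROIs)
study_scene <- function(...) scene_spec(...)

# one-ROI scene for fast amplitude-recovery checks
one_roi_scene <- function(amp_c1c2 = 0.4, amp_blank = 0.4, grid = c(8, 8, 4)) {
  scene_spec(grid = grid, rois = list(
    roi_spec("MT+ L", c(4, 4, 2), 1, amp_c1c2 = amp_c1c2, amp_blank = amp_blank)),
    calcarine_prior = cbind(min = c(1L, 1L, 1L), max = grid))
}

# V1-only scene (for seed tests)
v1_only_scene <- function(amp_blank = 0.5, grid = c(12, 12, 6)) {
  scene_spec(grid = grid, rois = list(
    roi_spec("V1", c(6, 4, 3), 2, amp_c1c2 = 0.2, amp_blank = amp_blank)),
    calcarine_prior = cbind(min = c(3L, 1L, 1L), max = c(9L, 7L, 6L)))
}

# tiny scene with single-voxel ROIs for fast resting-state cohorts
tiny_rest_scene <- function(grid = c(9, 9, 4)) {
  a <- grid[1] - 1; b <- grid[2] - 1
  mx <- ceiling(grid[1] / 2); my <- ceiling(grid[2] / 2)
  pos <- list(c(2, 2, 2), c(a, 2, 2), c(mx, my, 2), c(2, b, 2),
              c(a, b, 2), c(mx, 2, grid[3] - 1), c(mx, b, grid[3] - 1))
  scene_spec(grid = grid, rois = Map(function(lab, p) {
    roi_spec(lab, p, 0, amp_c1c2 = 0.4, amp_blank = 0.4)
  }, ROI_ORDER, pos),
    calcarine_prior = cbind(min = c(1L, 1L, 1L), max = grid))
}

# named ground-truth ROI list for a scene, in connectivity order
scene_rois_named <- function(scene) {
  setNames(lapply(ROI_ORDER, function(l) scene_roi(scene, l)), ROI_ORDER)
}

# target correlation matrix in scene ROI order with one imposed pair
target_with_pair <- function(scene, lab_a, lab_b, r) {
  labs <- vapply(scene$rois, `[[`, "", "label")
  k <- length(labs)
  m <- diag(k)
  i <- match(lab_a, labs); j <- match(lab_b, labs)
  m[i, j] <- m[j, i] <- r
  m
}

# a bold_run wrapped around an explicit time x voxel matrix (no dummies)
matrix_run <- function(Y, dim3, tr_s = 3, schedule = NULL) {
  arr <- array(0, c(dim3, nrow(Y)))
  arr[] <- t(Y)
  bold_run(arr, tr_s, 0, schedule)
}

quiet_motion <- function(n, seed = 1) {
  simulate_motion_trace(n, drift_sd = 0.005, seed = seed)
}

# simulate one subject's two stimulus series and run the full pipeline
simulate_and_run_subject <- function(scene, seed, noise = noise_spec(),
                                     config = default_config()) {
  sched <- make_condition_schedule()
  sb <- simulate_block_run(scene, sched, "stim_vs_blank", noise = noise, seed = seed)
  sr <- simulate_block_run(scene, sched, "c1_vs_c2", noise = noise, seed = seed + 5000L)
  suppressMessages(run_stimulus_pipeline(
    list(run = sb$run, motion = sb$motion),
    list(run = sr$run, motion = sr$motion), scene, config = config))
}
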
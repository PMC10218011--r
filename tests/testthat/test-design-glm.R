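test_that("the design has 1 interest + 6 motion + 4 Fourier + 1 constant columns", {
  sched <- make_condition_schedule()
  des <- build_design(sched, motion_trace = quiet_motion(84))
  expect_equal(ncol(des$X), 12)
  expect_equal(nrow(des$X), 84)
  expect_equal(des$columns[1], "task")
  expect_true("constant" %in% des$columns)
})

test_that("constant motion regressors are dropped with a warning, rank preserved", {
  sched <- make_condition_schedule()
  zero <- as_motion_trace(matrix(0, 84, 6))
  expect_warning(des <- build_design(sched, motion_trace = zero),
                 "constant motion regressor")
  expect_equal(ncol(des$X), 6)  # task + 4 Fourier + constant
  expect_equal(qr(des$X)$rank, ncol(des$X))
})

test_that("a duplicated regressor triggers a rank-deficiency error naming the column", {
  sched <- make_condition_schedule()
  mt <- as.matrix(quiet_motion(84))
  mt[, 2] <- mt[, 1]  # collinear pair
  expect_error(build_design(sched, motion_trace = as_motion_trace(mt)),
               "collinear.*motion")
})

test_that("the interest regressor lags the boxcar by the HRF effective delay", {
  sched <- make_condition_schedule()
  box <- boxcar_regressor(sched)
  reg <- convolve_hrf(box, default_hrf())
  lags <- 0:13
  cc <- vapply(lags, function(L) {
    cor(reg[(1 + L):84], box[1:(84 - L)])
  }, 1)
  peak <- lags[which.max(cc)]
  delay_trs <- 64 / (360 * 6 / 84)  # 64 degrees in TRs at the fundamental
  expect_lte(abs(peak - delay_trs), 1)
  expect_gt(peak, 0)
})

test_that("noiseless amplitudes are recovered exactly and PIVC keeps its negative sign", {
  scene <- study_scene()
  sched <- make_condition_schedule()
  sim <- simulate_block_run(scene, sched, "c1_vs_c2",
                            noise = noise_spec(0, 0, 0), seed = 8)
  des <- build_design(sched)
  sm <- fit_glm(sim$run, des)
  for (lab in c("MT+ L", "V6 R", "V1")) {
    i <- match(lab, vapply(scene$rois, `[[`, "", "label"))
    vox <- which(scene$membership == i)
    expect_equal(unname(sm$beta[vox]), rep(scene$rois[[i]]$amp_c1c2, length(vox)),
                 tolerance = 1e-9)
  }
  pivc <- scene_roi_voxels(scene, "PIVC L")
  expect_true(all(sm$beta[pivc] < 0))
  expect_true(all(sm$t[pivc] == -Inf))   # noiseless flagged
  expect_true(all(sm$p[pivc] == 0))
})

test_that("GLM residuals are orthogonal to every design column", {
  sched <- make_condition_schedule()
  des <- build_design(sched, motion_trace = quiet_motion(84))
  set.seed(21)
  Y <- matrix(rnorm(84 * 50), 84, 50)
  sm <- fit_glm(Y, des)
  coefs <- qr.coef(qr(des$X), Y)
  res <- Y - des$X %*% coefs
  expect_lt(max(abs(crossprod(des$X, res))), 1e-8)
})

test_that("low-frequency drifts within two cycles/run are absorbed exactly", {
  scene <- one_roi_scene(amp_c1c2 = 0.5)
  sched <- make_condition_schedule()
  sim <- simulate_block_run(scene, sched, "c1_vs_c2",
                            noise = noise_spec(0, 0, 0), seed = 2)
  Y <- boldflow:::run_matrix(sim$run)
  tt <- seq_len(84)
  drift <- 3 * sin(2 * pi * 2 * tt / 84 + 0.7) + 2 * cos(2 * pi * tt / 84)
  Yd <- Y + drift
  des <- build_design(sched)
  vox <- scene_roi_voxels(scene, "MT+ L")
  b0 <- fit_glm(Y, des)$beta_raw[vox]
  b1 <- fit_glm(Yd, des)$beta_raw[vox]
  expect_equal(b1, b0, tolerance = 1e-9)
})

test_that("pure-noise GLM maps are calibrated: ~5% false positives at p < 0.05", {
  sched <- make_condition_schedule()
  des <- build_design(sched, motion_trace = quiet_motion(84))
  set.seed(31)
  Y <- matrix(rnorm(84 * 2000), 84, 2000)
  sm <- fit_glm(Y, des)
  expect_lt(abs(mean(sm$p < 0.05) - 0.05), 0.02)
})

test_that("threshold_map honors the inclusive threshold and sign filters", {
  sched <- make_condition_schedule()
  des <- build_design(sched)
  set.seed(41)
  Y <- matrix(rnorm(84 * 200), 84, 200)
  sm <- fit_glm(Y, des)
  expect_equal(threshold_map(sm, 1.0), seq_len(200))
  expect_length(threshold_map(sm, 0), 0)
  pos <- threshold_map(sm, 0.2, "pos")
  neg <- threshold_map(sm, 0.2, "neg")
  expect_true(all(sm$t[pos] > 0))
  expect_true(all(sm$t[neg] < 0))
  expect_length(intersect(pos, neg), 0)
})

test_that("t-to-Z conversion is monotone, sign-symmetric and underflow-safe", {
  t <- c(-50, -3, -1, 0, 1, 3, 50)
  z <- t_to_z(t, 80)
  expect_true(all(diff(z) > 0))
  expect_lt(max(abs(z + rev(z))), 1e-8)
  expect_true(all(is.finite(z)))
  expect_gt(z[7], 10)  # large t maps to large finite Z, not Inf/NaN
})
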
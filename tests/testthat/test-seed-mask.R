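test_that("a noiseless V1-only scene yields a seed equal to the true V1 voxel set", {
  scene <- v1_only_scene()
  sched <- make_condition_schedule()
  sim <- simulate_block_run(scene, sched, "stim_vs_blank",
                            noise = noise_spec(0, 0, 0), seed = 1)
  sm <- fit_glm(sim$run, build_design(sched))
  whole_grid <- cbind(min = c(1L, 1L, 1L), max = scene$grid)
  seed <- define_v1_seed(sm, whole_grid)
  expect_equal(seed$voxels, scene_roi_voxels(scene, "V1"))
  expect_equal(seed$label, "V1")
})

test_that("an empty suprathreshold set inside the prior raises an informative error", {
  scene <- v1_only_scene(amp_blank = 0)   # no signal anywhere
  sched <- make_condition_schedule()
  sim <- simulate_block_run(scene, sched, "stim_vs_blank",
                            noise = noise_spec(0.2, 0, 0), seed = 2)
  sm <- fit_glm(sim$run, build_design(sched))
  expect_error(define_v1_seed(sm, scene$calcarine_prior, p_threshold = 1e-12),
               "threshold|prior")
})

test_that("the seed covers at least 80% of the true V1 voxels at default amplitudes", {
  scene <- study_scene()
  sched <- make_condition_schedule()
  truth <- scene_roi_voxels(scene, "V1")
  overlap <- vapply(1:5, function(s) {
    sim <- simulate_block_run(scene, sched, "stim_vs_blank", seed = 300 + s)
    sm <- fit_glm(sim$run, build_design(sched))
    seed <- define_v1_seed(sm, scene$calcarine_prior)
    mean(truth %in% seed$voxels)
  }, 1)
  expect_gte(mean(overlap), 0.8)
})

test_that("lagged correlation is 1 for the seed itself and for a one-TR-delayed copy", {
  n <- 84
  set.seed(6)
  # high-frequency seed so the two-cycle high-pass leaves it untouched
  seedtc <- cos(2 * pi * 6 * seq_len(n) / n) + 0.3 * cos(2 * pi * 11 * seq_len(n) / n + 1)
  delayed <- seedtc[c(n, 1:(n - 1))]
  Y <- cbind(seedtc, delayed, rnorm(n))
  run <- matrix_run(100 + Y, c(3, 1, 1))
  map <- lagged_correlation_map(run, seedtc, lags_s = c(0, 3))
  expect_equal(map$r[1, 1], 1, tolerance = 1e-9)   # identical voxel, lag 0
  expect_equal(map$r[2, 2], 1, tolerance = 1e-6)   # delayed voxel, lag 3 s
  expect_lt(abs(map$r[3, 1]), 0.5)
})

test_that("constant voxels get r = 0 and p = 1 rather than failing", {
  n <- 84
  set.seed(7)
  Y <- cbind(rep(5, n), rnorm(n))
  run <- matrix_run(Y, c(2, 1, 1))
  map <- lagged_correlation_map(run, rnorm(n))
  expect_equal(map$r[1, ], c(0, 0))
  expect_equal(map$p[1, ], c(1, 1))
})

test_that("independent-noise voxels are included at about the nominal 5% rate per lag", {
  n <- 84
  set.seed(8)
  rates <- sapply(1:4, function(rep) {
    Y <- matrix(rnorm(n * 1000), n, 1000)
    run <- matrix_run(Y, c(10, 10, 10))
    map <- lagged_correlation_map(run, rnorm(n))
    colMeans(map$p < 0.05)
  })
  expect_lt(abs(mean(rates[1, ]) - 0.05), 0.02)
  expect_lt(abs(mean(rates[2, ]) - 0.05), 0.02)
})

test_that("the union mask is the union of the per-lag significant sets", {
  fake <- structure(list(
    r = cbind(c(0.9, 0.1, -0.8, 0.2), c(0.1, 0.9, 0.1, 0.2)),
    p = cbind(c(0.01, 0.9, 0.01, 0.9), c(0.9, 0.01, 0.9, 0.9)),
    lags_s = c(0, 3), n_eff = c(84, 83), dim = c(4, 1, 1)),
    class = "lag_corr_map")
  expect_equal(union_mask(fake, 0.05), c(1L, 2L, 3L))        # both signs
  expect_equal(union_mask(fake, 0.05, sign = "pos"), c(1L, 2L))
  empty <- fake; empty$p[] <- 1
  expect_length(union_mask(empty, 0.05), 0)
})

test_that("the union mask is monotone in the threshold", {
  n <- 84
  set.seed(9)
  Y <- matrix(rnorm(n * 500), n, 500)
  run <- matrix_run(Y, c(10, 10, 5))
  map <- lagged_correlation_map(run, rnorm(n))
  m1 <- union_mask(map, 0.01)
  m2 <- union_mask(map, 0.05)
  m3 <- union_mask(map, 0.2)
  expect_true(all(m1 %in% m2))
  expect_true(all(m2 %in% m3))
})

test_that("noiseless labeling recovers every ROI voxel set exactly", {
  scene <- study_scene()
  sched <- make_condition_schedule()
  sim <- simulate_block_run(scene, sched, "c1_vs_c2",
                            noise = noise_spec(0, 0, 0), seed = 3)
  sm <- fit_glm(sim$run, build_design(sched))
  mask <- seq_len(prod(scene$grid))
  rois <- label_rois(sm, mask, scene)
  expect_setequal(vapply(rois, `[[`, "", "label"),
                  vapply(scene$rois, `[[`, "", "label"))
  for (r in rois) {
    expect_equal(r$voxels, scene_roi_voxels(scene, r$label))
    true_sign <- sign(scene$rois[[match(r$label,
                   vapply(scene$rois, `[[`, "", "label"))]]$amp_c1c2)
    expect_equal(r$sign, true_sign)
  }
})

test_that("an ROI with zero amplitude is absent from the labeling", {
  rois <- default_rois()
  i <- which(vapply(rois, `[[`, "", "label") == "V6 L")
  rois[[i]]$amp_c1c2 <- 0
  scene <- scene_spec(rois = rois)
  sched <- make_condition_schedule()
  sim <- simulate_block_run(scene, sched, "c1_vs_c2",
                            noise = noise_spec(0, 0, 0), seed = 4)
  sm <- fit_glm(sim$run, build_design(sched))
  labs <- vapply(label_rois(sm, seq_len(prod(scene$grid)), scene), `[[`, "", "label")
  expect_false("V6 L" %in% labs)
  expect_true("V6 R" %in% labs)
})

test_that("relaxing the threshold to 1 makes the sign-coherent foci tile the whole mask", {
  scene <- study_scene()
  sched <- make_condition_schedule()
  sim <- simulate_block_run(scene, sched, "c1_vs_c2",
                            noise = noise_spec(0, 0, 0), seed = 5)
  sm <- fit_glm(sim$run, build_design(sched))
  mask <- which(scene$membership > 0)
  rois <- suppressMessages(label_rois(sm, mask, scene, p_threshold = 1))
  expect_equal(sort(unlist(lapply(rois, `[[`, "voxels"))), mask)
})
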
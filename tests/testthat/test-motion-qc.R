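test_that("FD matches hand evaluation of the displacement sum", {
  # constant trace: FD identically zero
  const <- as_motion_trace(matrix(rep(c(1, 2, 3, 4, 5, 6), each = 10), 10, 6))
  expect_equal(framewise_displacement(const)$fd, rep(0, 10))

  # translation deltas (0.2, 0.1, 0.1) mm, rotations constant -> FD = 0.4 mm
  tr <- as_motion_trace(rbind(c(0, 0, 0, 1, 1, 1),
                              c(0.2, 0.1, -0.1, 1, 1, 1)))
  expect_equal(framewise_displacement(tr)$fd, c(0, 0.4), tolerance = 1e-12)

  # rotation deltas of 0.01 rad each at radius 50 mm -> FD = 3 * 50 * 0.01
  d <- 0.01 * 180 / pi
  tr2 <- as_motion_trace(rbind(c(0, 0, 0, 0, 0, 0),
                               c(0, 0, 0, d, d, d)))
  expect_equal(framewise_displacement(tr2, radius_mm = 50)$fd, c(0, 1.5),
               tolerance = 1e-12)
})

test_that("FD is invariant to constant offsets and linear in radius for rotations", {
  set.seed(11)
  tr <- simulate_motion_trace(40, drift_sd = 0.05, seed = 11)
  fd0 <- framewise_displacement(tr)$fd
  shifted <- as.matrix(tr)
  shifted <- sweep(shifted, 2, c(3, -2, 1, 10, -5, 0.3), `+`)
  expect_equal(framewise_displacement(as_motion_trace(shifted))$fd, fd0,
               tolerance = 1e-12)

  rot_only <- as.matrix(tr)
  rot_only[, 1:3] <- 0
  f1 <- framewise_displacement(as_motion_trace(rot_only), radius_mm = 50)$fd
  f2 <- framewise_displacement(as_motion_trace(rot_only), radius_mm = 100)$fd
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
})

test_that("FD needs at least two time points", {
  expect_error(framewise_displacement(matrix(0, 1, 6)), "length >= 2")
})

test_that("suprathreshold counting uses a strict inequality", {
  expect_equal(count_suprathreshold(c(0.1, 0.6, 0.7), 0.5), 2)
  expect_equal(count_suprathreshold(c(0.1, 0.2, 0.5), 0.5), 0)
})

test_that("screening keeps quiet runs with one interval covering the run", {
  tr <- simulate_motion_trace(88, drift_sd = 0.005, seed = 3)
  res <- screen_run(tr)
  expect_equal(res$verdict, "keep")
  expect_equal(unname(res$intervals[1, ]), c(1L, 88L))
})

test_that("screening excludes a run drifting beyond the translation limit", {
  m <- matrix(0, 88, 6)
  m[, 3] <- seq(0, 4.5, length.out = 88)  # slow 4.5 mm drift, always 'still'
  res <- screen_run(as_motion_trace(m))
  expect_equal(res$verdict, "exclude")
  expect_equal(nrow(res$intervals), 0)
})

test_that("a mid-run movement burst segments the run into two retained intervals", {
  set.seed(5)
  m <- as.matrix(simulate_motion_trace(88, drift_sd = 0.003, seed = 5))
  m[41:44, 1] <- m[41:44, 1] + c(2, 2.5, 2.2, 2.4)  # 4-point burst, then return
  res <- screen_run(as_motion_trace(m))
  expect_equal(res$verdict, "segment")
  expect_equal(nrow(res$intervals), 2)
  expect_true(all(res$intervals[1, ] < 41))
  expect_true(res$intervals[2, 1] > 44)
  # retained intervals are disjoint and ordered
  expect_true(res$intervals[1, 2] < res$intervals[2, 1])
})

test_that("motion summary of a single constant trace is all zeros", {
  const <- as_motion_trace(matrix(rep(c(1, 2, 3, 4, 5, 6), each = 20), 20, 6))
  s <- summarize_motion(list(const))
  expect_equal(unname(unlist(s[, c("tx_mean", "ty_mean", "tz_mean",
                                   "rx_mean", "ry_mean", "rz_mean",
                                   "fd_mean", "n_supra_mean")])),
               rep(0, 8))
})

test_that("motion summary has the per-direction / FD / count column layout", {
  s <- summarize_motion(list(quiet_motion(88, 1), quiet_motion(88, 2)),
                        group = c("5w", "5w"), series = c("rest", "rest"))
  expect_named(s, c("group", "series", "n_traces",
                    "tx_mean", "tx_sd", "ty_mean", "ty_sd", "tz_mean", "tz_sd",
                    "rx_mean", "rx_sd", "ry_mean", "ry_sd", "rz_mean", "rz_sd",
                    "fd_mean", "fd_sd", "n_supra_mean", "n_supra_sd"))
  expect_equal(nrow(s), 1)
})

test_that("group FD mean of quiet generated traces matches the analytic expectation", {
  # FD of iid Gaussian increments with SD s on 6 parameters:
  # E[FD] = 3 s sqrt(2/pi) (1 + radius * pi / 180), scaled by (n-1)/n
  # because the first FD is 0 by convention
  s_inc <- 0.01; n <- 88
  traces <- lapply(1:40, function(i) simulate_motion_trace(n, s_inc, seed = i))
  got <- summarize_motion(traces)$fd_mean
  expected <- 3 * s_inc * sqrt(2 / pi) * (1 + 50 * pi / 180) * (n - 1) / n
  expect_lt(abs(got - expected), 0.1 * expected)
})
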
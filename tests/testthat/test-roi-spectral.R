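test_that("a constant run extracts an all-zero percent time course", {
  Y <- matrix(500, 84, 4)
  run <- matrix_run(Y, c(2, 2, 1))
  expect_equal(extract_timecourse(run, 1:4), rep(0, 84))
  expect_error(extract_timecourse(run, integer(0)), "empty")
})

test_that("an ROI mixing 0.4% and 0.8% voxels recovers a 0.6% amplitude", {
  sched <- make_condition_schedule()
  reg <- convolve_hrf(boxcar_regressor(sched), default_hrf())
  base <- 1000
  Y <- cbind(base * (1 + 0.4 / 100 * reg), base * (1 + 0.8 / 100 * reg))
  run <- matrix_run(Y, c(2, 1, 1))
  tc <- extract_timecourse(run, 1:2)
  amp <- unname(coef(lm(tc ~ reg))[2])
  expect_equal(amp, 0.6, tolerance = 0.01)
})

test_that("period splitting flags exactly the fully retained periods", {
  sched <- make_condition_schedule()
  tc <- rnorm(84)
  expect_equal(split_periods(tc, sched)$good, 1:6)

  # burst spanning period 3 (TRs 29-42): two retained intervals around it
  scr <- structure(list(verdict = "segment",
                        intervals = cbind(start = c(1L, 43L), end = c(28L, 84L)),
                        reason = "fixture"), class = "screen_result")
  expect_equal(split_periods(tc, sched, scr)$good, c(1, 2, 4, 5, 6))

  # retained span covering 3.5 periods -> 3 usable full periods
  scr2 <- structure(list(verdict = "segment",
                         intervals = cbind(start = 1L, end = 49L),
                         reason = "fixture"), class = "screen_result")
  expect_equal(split_periods(tc, sched, scr2)$good, 1:3)

  scr3 <- structure(list(verdict = "segment",
                         intervals = cbind(start = 2L, end = 13L),
                         reason = "fixture"), class = "screen_result")
  expect_error(split_periods(tc, sched, scr3), "no good")
})

test_that("period averaging: identical periods give SD 0; two periods average pointwise", {
  one <- sin(seq_len(14))
  pm <- matrix(rep(one, each = 6), 6, 14, byrow = FALSE)
  pm <- matrix(one, 6, 14, byrow = TRUE)
  pa <- period_average(pm)
  expect_equal(pa$mean, one)
  expect_equal(pa$sd, rep(0, 14))

  two <- rbind(a = rep(1, 14), b = rep(3, 14))
  expect_equal(period_average(two)$mean, rep(2, 14))
})

test_that("period-average SD shrinks as 1/sqrt(n) across periods", {
  set.seed(13)
  sems <- vapply(c(4, 16), function(np) {
    reps <- replicate(300, {
      pm <- matrix(rnorm(np * 14), np, 14)
      mean(period_average(pm)$mean^2)
    })
    sqrt(mean(reps))
  }, 1)
  expect_equal(sems[1] / sems[2], 2, tolerance = 0.15)
})

test_that("the windowed mean response uses inclusive 1-based TRs 3 to 6", {
  flat <- structure(list(mean = rep(1, 14), sd = rep(0, 14), n_periods = 6),
                    class = "period_average")
  expect_equal(mean_response(flat), 1)
  ramp <- structure(list(mean = 0:13, sd = rep(0, 14), n_periods = 6),
                    class = "period_average")
  expect_equal(mean_response(ramp), (2 + 3 + 4 + 5) / 4)  # = 3.5
})

test_that("the windowed mean of a noiseless 0.5% simulation equals the regressor window mean", {
  scene <- one_roi_scene(amp_c1c2 = 0.5)
  sched <- make_condition_schedule()
  sim <- simulate_block_run(scene, sched, "c1_vs_c2",
                            noise = noise_spec(0, 0, 0), seed = 1)
  tc <- extract_timecourse(sim$run, scene_roi_voxels(scene, "MT+ L"))
  pa <- period_average(split_periods(tc, sched))
  reg <- convolve_hrf(boxcar_regressor(sched), default_hrf())
  # closed form: percent series is 0.5 (reg - mean reg) / (1 + 0.5 mean(reg)/100)
  expected <- mean(vapply(3:6, function(tr) {
    mean(reg[tr + 14 * (0:5)]) - mean(reg)
  }, 1)) * 0.5 / (1 + 0.5 * mean(reg) / 100)
  expect_equal(mean_response(pa), expected, tolerance = 1e-9)
})

test_that("spectral summary: pure fundamental cosine reads phase 0 and huge SNR", {
  n <- 84
  x <- cos(2 * pi * 6 * seq_len(n) / n)
  # reference boxcar phase: compare against a boxcar-locked cosine instead
  s <- spectral_summary(x + 1e-6 * rnorm(n), 6)
  expect_gt(s$snr, 100)
  box <- rep(rep(c(1, 0), each = 7), 6)
  x_locked <- box - mean(box)
  s2 <- spectral_summary(x_locked, 6)
  expect_lt(min(s2$phase_deg, 360 - s2$phase_deg), 1)  # phase ~ 0 vs C1 onset
  expect_lt(s2$p, 0.01)
})

test_that("fewer than two periods is an error (neighbour bins undefined)", {
  expect_error(spectral_summary(rnorm(14), 1), "at least 2")
})

test_that("white-noise SNR matches the independent three-bin null within MC error", {
  set.seed(17)
  med_impl <- median(replicate(800, spectral_summary(rnorm(84), 6)$snr))
  z <- matrix(complex(real = rnorm(3 * 20000), imaginary = rnorm(3 * 20000)),
              ncol = 3)
  med_oracle <- median(Mod(z[, 2]) / sqrt((Mod(z[, 1])^2 + Mod(z[, 3])^2) / 2))
  expect_lt(abs(med_impl - med_oracle), 0.08)
  expect_lt(abs(med_impl - 1), 0.2)   # all three bins share the same noise law
})

test_that("the calibrated model response reads 64 degrees, shifted runs shift accordingly", {
  sched <- make_condition_schedule()
  box <- boxcar_regressor(sched)
  reg <- convolve_hrf(box, default_hrf())
  s <- spectral_summary(reg - mean(reg), 6)
  expect_lt(abs(s$phase_deg - 64), 3)
  # delaying by k TRs adds k * 360/14 degrees (mod 360)
  for (k in c(1, 5)) {
    rk <- reg[((seq_len(84) - 1 - k) %% 84) + 1]
    sk <- spectral_summary(rk - mean(rk), 6)
    expect_equal((sk$phase_deg - s$phase_deg) %% 360, (k * 360 / 14) %% 360,
                 tolerance = 1e-6)
  }
})

test_that("SNR is invariant to rescaling and Parseval holds to machine precision", {
  set.seed(19)
  x <- rnorm(84)
  s1 <- spectral_summary(x, 6)
  s2 <- spectral_summary(17.3 * x, 6)
  expect_equal(s1$snr, s2$snr, tolerance = 1e-12)
  expect_equal(sum(Mod(fft(x))^2) / 84, sum(x^2), tolerance = 1e-9)
})

test_that("the windowed mean is maximal when the phase centers the response window", {
  # window TRs 3..6 has center 4.5 TR; a cosine peaking there has phase
  # 2*pi*(4.5 - 1)/14 relative to the series start (TR 1 samples phase 0)
  n <- 84
  shifts <- seq(0, 13, by = 0.5)
  vals <- vapply(shifts, function(d) {
    x <- cos(2 * pi * 6 * (seq_len(n) - 1 - d) / n)
    pa <- period_average(matrix(x, 6, 14, byrow = TRUE))
    mean_response(pa)
  }, 1)
  expect_equal(shifts[which.max(vals)], 3.5, tolerance = 0.5)
})

test_that("circular mean and SD follow the vector-resultant computation", {
  r <- circular_mean_sd(c(10, 50))
  expect_equal(r$mean_deg, 30, tolerance = 1e-9)
  r2 <- circular_mean_sd(120)
  expect_equal(r2$mean_deg, 120)
  expect_equal(r2$sd_deg, 0)
  r3 <- circular_mean_sd(c(350, 10))
  expect_lt(min(r3$mean_deg, 360 - r3$mean_deg), 1e-9)  # wraps correctly to 0
  expect_equal(r3$sd_deg, 10, tolerance = 1e-9)
  expect_warning(r4 <- circular_mean_sd(c(0, 180)), "zero resultant")
  expect_true(is.na(r4$mean_deg))
  # SNR-weighted mean pulls toward the heavier vector
  rw <- circular_mean_sd(c(0, 90), weights = c(3, 1))
  expect_lt(rw$mean_deg, 45)
})

test_that("group comparisons: identical groups give p ~ 1; amplitude power matches analytic", {
  same <- c(0.4, 0.5, 0.45, 0.5)
  expect_gt(compare_groups(same, same, "amplitude")$p, 0.99)
  expect_gt(compare_groups(c(10, 20, 30), c(10, 20, 30), "phase")$p, 0.99)

  # two-sample t power at delta 0.3, sd 0.15, n = 8 and 12
  set.seed(23)
  nrep <- 300
  rej <- mean(replicate(nrep, {
    a <- rnorm(8, 0.72, 0.15)
    b <- rnorm(12, 0.42, 0.15)
    compare_groups(a, b, "amplitude")$p < 0.05
  }))
  # exact noncentral-t power for the pooled two-sample test
  ncp <- 0.3 / (0.15 * sqrt(1 / 8 + 1 / 12))
  crit <- qt(0.975, 18)
  pw <- 1 - pt(crit, 18, ncp) + pt(-crit, 18, ncp)
  expect_lt(abs(rej - pw), 3 * sqrt(pw * (1 - pw) / nrep) + 0.03)
})

test_that("phase comparison detects a shifted group and respects wraparound", {
  set.seed(29)
  a <- (rnorm(12, 46, 30)) %% 360
  b <- (rnorm(12, 120, 30)) %% 360
  expect_lt(compare_groups(a, b, "phase")$p, 0.05)
  # groups straddling 0 degrees are compared on wrapped deviations
  a2 <- c(350, 355, 5, 10)
  b2 <- c(170, 175, 185, 190)
  expect_lt(compare_groups(a2, b2, "phase")$p, 0.01)
})
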
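# synthetic BOLD generators: block-design runs, resting-state runs, motion traces

#' Noise specification for synthetic runs
#'
#' White Gaussian noise (as percent of baseline), optionally AR(1)-filtered
#' (scaled to keep the stationary SD equal to \code{sd_pct}), plus a per-voxel
#' random slow drift, modeled as random-phase fluctuations at 1 and 2 cycles
#' per run - the band that scanner drift occupies and that the two-cycle
#' GLM-Fourier high-pass is designed to remove.
#'
#' @param sd_pct stationary noise SD, percent of baseline.
#' @param ar1 AR(1) coefficient in (-1, 1).
#' @param drift_pct approximate SD of the slow drift, percent of baseline.
#' @return a \code{noise_spec} list.
#' @export
noise_spec <- function(sd_pct = 0.2, ar1 = 0.3, drift_pct = 0.5) {
  stopifnot(sd_pct >= 0, drift_pct >= 0, abs(ar1) < 1)
  structure(list(sd_pct = sd_pct, ar1 = ar1, drift_pct = drift_pct),
            class = "noise_spec")
}

# n x m matrix of stationary AR(1) noise with unit marginal SD
ar1_noise <- function(n, m, rho) {
  e <- matrix(rnorm(n * m), n, m)
  if (rho == 0) return(e)
  e <- e * sqrt(1 - rho^2)
  apply(e, 2, function(col) as.numeric(stats::filter(col, rho, method = "recursive")))
}

# time x voxel noise matrix in percent-of-baseline units, plus slow drift
# (random-phase 1- and 2-cycle/run fluctuations, per voxel)
make_noise <- function(n, m, noise) {
  x <- ar1_noise(n, m, noise$ar1) * noise$sd_pct
  if (noise$drift_pct > 0) {
    tt <- seq_len(n)
    B <- cbind(sin(2 * pi * tt / n), cos(2 * pi * tt / n),
               sin(4 * pi * tt / n), cos(4 * pi * tt / n))
    coefs <- matrix(rnorm(4 * m, 0, noise$drift_pct / sqrt(2)), 4, m)
    x <- x + B %*% coefs
  }
  x
}

#' Construct a BOLD run container
#'
#' @param data 4D array (x, y, z, t) of signal intensities, dummies included.
#' @param tr_s repetition time (s).
#' @param n_dummy number of initial dummy volumes.
#' @param schedule the condition schedule, or NULL for resting state.
#' @param vox_mm voxel size (mm).
#' @return object of class \code{bold_run}.
#' @export
bold_run <- function(data, tr_s, n_dummy, schedule = NULL, vox_mm = 3) {
  stopifnot(length(dim(data)) == 4, n_dummy >= 0, tr_s > 0)
  structure(list(data = data, tr_s = tr_s, n_dummy = as.integer(n_dummy),
                 schedule = schedule, vox_mm = vox_mm,
                 dim = dim(data)[1:3], n_total = dim(data)[4],
                 n_retained = dim(data)[4] - as.integer(n_dummy)),
            class = "bold_run")
}

# retained time x voxel matrix of a run
run_matrix <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  d <- run$dim
  m <- matrix(run$data, prod(d), run$n_total)
  t(m[, (run$n_dummy + 1):run$n_total, drop = FALSE])
}

#' Simulate a block-design BOLD run
#'
#' Each ROI voxel carries \code{baseline * (1 + amp/100 * r(t))} where
#' \code{r} is the condition boxcar convolved with the HRF (the same
#' construction the design matrix uses, so noiseless runs are recovered
#' exactly); non-ROI voxels carry baseline and noise only.  A per-ROI extra
#' hemodynamic delay is applied as a circular Fourier shift of the convolved
#' regressor, which adds exactly \code{delay_s * 360 / period_s} degrees to
#' the fundamental phase.  Dummy volumes carry a decaying transient offset so
#' that dummy handling is exercised downstream.
#'
#' @param scene a \code{scene_spec}.
#' @param schedule a \code{condition_schedule}.
#' @param contrast which amplitude field drives the run: \code{"c1_vs_c2"}
#'   (coherent vs random motion) or \code{"stim_vs_blank"}.
#' @param hrf HRF kernel; default the calibrated canonical HRF.
#' @param noise a \code{noise_spec}; use \code{noise_spec(0, 0, 0)} for a
#'   noiseless run.
#' @param motion either a \code{motion_trace} of length
#'   \code{schedule$n_total} or a list of arguments for
#'   \code{\link{simulate_motion_trace}}.
#' @param seed integer RNG seed (reruns are bit-identical).
#' @return list with elements \code{run} (a \code{bold_run}), \code{motion}
#'   (a \code{motion_trace}) and \code{truth} (ground-truth record).
#' @export
simulate_block_run <- function(scene, schedule = make_condition_schedule(),
                               contrast = c("c1_vs_c2", "stim_vs_blank"),
                               hrf = default_hrf(), noise = noise_spec(),
                               motion = list(), seed = 1) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(scene, "scene_spec"), inherits(schedule, "condition_schedule"))
  set.seed(seed)
  nvox <- prod(scene$grid)
  nt <- schedule$n_retained
  box <- boxcar_regressor(schedule)
  reg <- convolve_hrf(box, hrf)

  amp_field <- if (contrast == "c1_vs_c2") "amp_c1c2" else "amp_blank"
  pct <- make_noise(nt, nvox, noise)   # time x voxel, percent units
  true_amp <- numeric(length(scene$rois))
  true_phase <- numeric(length(scene$rois))
  for (i in seq_along(scene$rois)) {
    r <- scene$rois[[i]]
    amp <- r[[amp_field]]
    reg_i <- if (r$delay_s != 0) fourier_shift(reg, r$delay_s / schedule$tr_s) else reg
    vox <- which(scene$membership == i)
    pct[, vox] <- pct[, vox] + amp * reg_i
    true_amp[i] <- amp
    true_phase[i] <- wrap_angle_360(
      fundamental_phase(reg, schedule$n_periods, box) +
        r$delay_s * 360 / schedule$period_s)
  }
  signal <- scene$baseline * (1 + pct / 100)

  # dummy volumes: baseline with a decaying 2% transient (no task signal)
  nd <- schedule$n_dummy
  dummies <- if (nd > 0) {
    off <- scene$baseline * (1 + 0.02 * exp(-(seq_len(nd) - 1)))
    matrix(rep(off, each = nvox), nvox, nd) +
      scene$baseline / 100 * matrix(rnorm(nvox * nd, 0, noise$sd_pct), nvox, nd)
  } else NULL

  data <- array(0, c(scene$grid, schedule$n_total))
  flat <- cbind(dummies, t(signal))
  data[] <- flat
  run <- bold_run(data, schedule$tr_s, nd, schedule, scene$vox_mm)

  if (inherits(motion, "motion_trace")) {
    trace <- motion
    spikes <- attr(motion, "spike_times")
  } else {
    margs <- utils::modifyList(
      list(n_timepoints = schedule$n_total, seed = seed + 1L), as.list(motion))
    trace <- do.call(simulate_motion_trace, margs)
    spikes <- attr(trace, "spike_times")
  }

  truth <- list(
    labels = vapply(scene$rois, `[[`, "", "label"),
    amplitudes = true_amp, phases_deg = true_phase, contrast = contrast,
    membership = scene$membership, spike_times = spikes, seed = seed)
  list(run = run, motion = trace, truth = truth)
}

# circular shift of a periodic series by `lag` samples (possibly fractional)
# via the Fourier shift theorem; positive lag delays the series
fourier_shift <- function(x, lag) {
  n <- length(x)
  f <- stats::fft(x)
  k <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1))
  Re(stats::fft(f * exp(-2i * pi * k * lag / n), inverse = TRUE)) / n
}

#' Simulate a resting-state BOLD run with imposed ROI correlations
#'
#' Latent ROI signals are drawn with population correlation
#' \code{target_corr} (via its Cholesky factor) and written into the ROI
#' voxels at \code{signal_pct} percent of baseline; every voxel additionally
#' carries measurement noise.  Averaging an ROI of m voxels attenuates the
#' observed inter-ROI correlation by the computable factor
#' \code{sqrt(a_i * a_j)} with \code{a = s^2 / (s^2 + sd^2/m)}; the per-ROI
#' factors and the attenuated target matrix are returned in the ground truth
#' so recovery tests can correct for them.
#'
#' @param scene a \code{scene_spec}.
#' @param target_corr symmetric positive-semidefinite correlation matrix,
#'   one row per scene ROI, in scene ROI order.
#' @param n_timepoints total volumes including dummies (default 124).
#' @param n_dummy dummy volumes at the start (default 4).
#' @param signal_pct SD of the latent ROI fluctuation, percent of baseline.
#' @param noise a \code{noise_spec}.
#' @param seed RNG seed.
#' @return list with \code{run} (a \code{bold_run}) and \code{truth}
#'   (including \code{attenuation} and \code{expected_corr}).
#' @export
simulate_rest_run <- function(scene, target_corr, n_timepoints = 124,
                              n_dummy = 4, signal_pct = 1, noise = noise_spec(),
                              seed = 1) {
  stopifnot(inherits(scene, "scene_spec"))
  k <- length(scene$rois)
  stopifnot(is.matrix(target_corr), dim(target_corr) == c(k, k))
  if (max(abs(target_corr - t(target_corr))) > 1e-8 ||
      max(abs(diag(target_corr) - 1)) > 1e-8) {
    stop("target_corr must be symmetric with unit diagonal")
  }
  ev <- eigen(target_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("target_corr is not positive semidefinite")

  set.seed(seed)
  nt <- n_timepoints - n_dummy
  nvox <- prod(scene$grid)
  # latent ROI signals: unit-SD AR(1) innovations mixed by the PSD square root
  ed <- eigen(target_corr, symmetric = TRUE)
  sq <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), k) %*% t(ed$vectors)
  latent <- ar1_noise(nt, k, noise$ar1) %*% sq   # time x roi

  pct <- make_noise(nt, nvox, noise)
  m_vox <- integer(k)
  for (i in seq_len(k)) {
    vox <- which(scene$membership == i)
    m_vox[i] <- length(vox)
    pct[, vox] <- pct[, vox] + signal_pct * latent[, i]
  }
  signal <- scene$baseline * (1 + pct / 100)

  dummies <- if (n_dummy > 0) {
    off <- scene$baseline * (1 + 0.02 * exp(-(seq_len(n_dummy) - 1)))
    matrix(rep(off, each = nvox), nvox, n_dummy)
  } else NULL
  data <- array(0, c(scene$grid, n_timepoints))
  data[] <- cbind(dummies, t(signal))
  run <- bold_run(data, 3, n_dummy, NULL, scene$vox_mm)

  atten <- signal_pct^2 / (signal_pct^2 + noise$sd_pct^2 / m_vox)
  expected <- target_corr * sqrt(outer(atten, atten))
  diag(expected) <- 1
  truth <- list(labels = vapply(scene$rois, `[[`, "", "label"),
                target_corr = target_corr, attenuation = atten,
                expected_corr = expected, seed = seed)
  list(run = run, truth = truth)
}

#' Simulate a six-parameter head-motion trace
#'
#' A smooth low-amplitude random wander (cumulative sum of small Gaussian
#' increments) on each of the six rigid-body parameters, plus optional
#' step-like spikes: at each spike time one translation axis jumps by
#' \code{spike_mag} mm and stays, producing exactly one suprathreshold
#' framewise-displacement event per spike.  Spike times are recorded in the
#' \code{spike_times} attribute.
#'
#' @param n_timepoints trace length.
#' @param drift_sd SD of the per-TR wander increments (mm for translations;
#'   degrees for rotations use the same numeric value).
#' @param spike_rate expected number of spikes per run (Poisson), ignored if
#'   \code{spike_times} is given.
#' @param spike_mag spike step size in mm.
#' @param spike_times optional integer vector of spike time indices (>= 2).
#' @param seed RNG seed.
#' @return a \code{motion_trace}: data.frame with columns dx, dy, dz (mm) and
#'   rx, ry, rz (degrees), one row per time point.
#' @export
simulate_motion_trace <- function(n_timepoints, drift_sd = 0.01,
                                  spike_rate = 0, spike_mag = 2,
                                  spike_times = NULL, seed = 1) {
  stopifnot(n_timepoints >= 2, drift_sd >= 0, spike_rate >= 0, spike_mag >= 0)
  set.seed(seed)
  tr <- as.data.frame(apply(matrix(rnorm(n_timepoints * 6, 0, drift_sd),
                                   n_timepoints, 6), 2, cumsum))
  names(tr) <- c("dx", "dy", "dz", "rx", "ry", "rz")
  if (is.null(spike_times) && spike_rate > 0) {
    n_sp <- stats::rpois(1, spike_rate)
    if (n_sp > 0) spike_times <- sort(sample(2:n_timepoints, min(n_sp, n_timepoints - 1)))
  }
  if (length(spike_times)) {
    stopifnot(all(spike_times >= 2), all(spike_times <= n_timepoints))
    axes <- sample(1:3, length(spike_times), replace = TRUE)
    for (s in seq_along(spike_times)) {
      idx <- spike_times[s]:n_timepoints
      tr[idx, axes[s]] <- tr[idx, axes[s]] + spike_mag * sample(c(-1, 1), 1)
    }
  }
  structure(tr, class = c("motion_trace", "data.frame"),
            spike_times = as.integer(spike_times))
}

#' Coerce a 6-column table to a motion trace
#' @param x matrix or data.frame with 6 columns (dx, dy, dz in mm; rx, ry, rz
#'   in degrees).
#' @return a \code{motion_trace}.
#' @export
as_motion_trace <- function(x) {
  x <- as.data.frame(x)
  stopifnot(ncol(x) == 6)
  names(x) <- c("dx", "dy", "dz", "rx", "ry", "rz")
  stopifnot(all(vapply(x, is.numeric, TRUE)), all(is.finite(as.matrix(x))))
  structure(x, class = c("motion_trace", "data.frame"))
}
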
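# ROI time courses, period averaging, spectral SNR/phase, circular statistics

#' Extract the percent-signal-change time course of an ROI
#'
#' Spatial mean over the ROI voxels on the retained time points, converted to
#' percent of the ROI temporal mean.
#'
#' @param run a \code{bold_run}.
#' @param roi an \code{roi} or integer vector of voxel indices.
#' @return numeric percent series of length \code{run$n_retained}.
#' @export
extract_timecourse <- function(run, roi) {
  stopifnot(inherits(run, "bold_run"))
  vox <- if (inherits(roi, "roi")) roi$voxels else as.integer(roi)
  if (length(vox) == 0) stop("ROI is empty")
  stopifnot(all(vox >= 1), all(vox <= prod(run$dim)))
  m <- rowMeans(run_matrix(run)[, vox, drop = FALSE])
  100 * (m / mean(m) - 1)
}

#' Split a time course into stimulus periods and flag the good ones
#'
#' A period (one C1 block + one C2 block, 14 TRs by default) is "good" iff it
#' lies entirely inside one retained interval of the motion screening; partial
#' periods are excluded.
#'
#' @param tc ROI time course (retained points).
#' @param schedule a \code{condition_schedule}.
#' @param screen_result optional \code{screen_result} (in retained-point
#'   indexing); NULL means the full run is retained.
#' @return list with \code{periods} (n_periods x period_len matrix),
#'   \code{good} (integer indices of good periods).
#' @export
split_periods <- function(tc, schedule, screen_result = NULL) {
  stopifnot(inherits(schedule, "condition_schedule"),
            length(tc) == schedule$n_retained)
  pl <- schedule$period_len
  periods <- matrix(tc, nrow = schedule$n_periods, ncol = pl, byrow = TRUE)
  if (is.null(screen_result)) {
    good <- seq_len(schedule$n_periods)
  } else {
    iv <- screen_result$intervals
    good <- which(vapply(seq_len(schedule$n_periods), function(p) {
      a <- (p - 1L) * pl + 1L
      b <- p * pl
      any(iv[, 1] <= a & iv[, 2] >= b)
    }, TRUE))
  }
  if (length(good) == 0) stop("no good stimulus periods after screening")
  list(periods = periods, good = good)
}

#' Average the response across good periods
#'
#' @param periods result of \code{split_periods}, or a periods x TR matrix.
#' @return a \code{period_average}: list with per-TR \code{mean} and \code{sd}
#'   across the good periods and \code{n_periods} used.
#' @export
period_average <- function(periods) {
  if (is.list(periods) && !is.null(periods$periods)) {
    m <- periods$periods[periods$good, , drop = FALSE]
  } else {
    m <- as.matrix(periods)
  }
  stopifnot(nrow(m) >= 1)
  structure(list(mean = colMeans(m),
                 sd = if (nrow(m) > 1) apply(m, 2, sd) else rep(0, ncol(m)),
                 n_periods = nrow(m)),
            class = "period_average")
}

#' Windowed mean response
#'
#' Mean of the per-TR period-average over an inclusive 1-based TR window,
#' default TRs 3 to 6 (9-18 s after C1 onset at TR 3 s).
#'
#' @param period_avg a \code{period_average}.
#' @param window integer TR indices (inclusive), default \code{3:6}.
#' @return scalar percent signal change.
#' @export
mean_response <- function(period_avg, window = 3:6) {
  stopifnot(inherits(period_avg, "period_average"),
            all(window >= 1), all(window <= length(period_avg$mean)))
  mean(period_avg$mean[window])
}

#' Spectral SNR and phase of an ROI time course
#'
#' The good periods are concatenated in order (keeping the fundamental on an
#' exact Fourier bin) and discretely Fourier transformed.  SNR is the
#' amplitude at the fundamental (n_periods cycles per series) divided by the
#' root-mean-square amplitude of the two adjacent bins.  The phase is
#' reported in degrees relative to C1 onset (via the condition boxcar over
#' the same series), with the convention that a delayed response has a larger
#' phase; a canonical hemodynamic response reads 64 degrees.  Significance is
#' a one-sided F(2, 4) test of the fundamental power against the mean of the
#' two neighbour-bin powers (each bin power is a scaled chi-square(2) under
#' Gaussian noise) - a reconstruction of the significance symbols used with
#' this statistic, documented as such.
#'
#' @param tc percent time course of the good periods, concatenated; length
#'   must equal \code{n_periods * period_len}.
#' @param n_periods number of (good) periods contained in \code{tc}; must be
#'   >= 2 so the neighbour bins exist within the signal band.
#' @param period_len period length in TRs (default 14).
#' @return a \code{spectral_summary}: list with \code{snr}, \code{phase_deg}
#'   in [0, 360), \code{fundamental} (cycles/series), \code{amplitude}
#'   (percent, peak amplitude of the fundamental component), \code{p}.
#' @export
spectral_summary <- function(tc, n_periods, period_len = 14) {
  if (n_periods < 2) stop("spectral summary needs at least 2 periods")
  n <- n_periods * period_len
  stopifnot(length(tc) == n)
  box <- rep(rep(c(1, 0), each = period_len / 2), n_periods)
  X <- stats::fft(tc)
  amps <- Mod(X)
  k <- n_periods + 1L           # fundamental bin (1-based; bin 1 is DC)
  neigh <- c(k - 1L, k + 1L)
  rms_neigh <- sqrt(mean(amps[neigh]^2))
  snr <- if (rms_neigh > 0) amps[k] / rms_neigh else Inf
  phase <- if (amps[k] > 0) {
    fundamental_phase(tc, n_periods, box)
  } else NA_real_
  ratio <- amps[k]^2 / mean(amps[neigh]^2)
  p <- pf(ratio, 2, 4, lower.tail = FALSE)
  structure(list(snr = snr, phase_deg = phase, fundamental = n_periods,
                 amplitude = 2 * amps[k] / n, p = p),
            class = "spectral_summary")
}

#' Circular mean and SD of phases
#'
#' Vector computation: the mean is the angle of the resultant of the (unit or
#' weighted) phase vectors; the SD is the root-mean-square of the wrapped
#' angular deviations from the mean, each in (-180, 180].
#'
#' @param phase_deg phases in degrees.
#' @param weights non-negative weights (e.g. SNR); default equal.
#' @return list with \code{mean_deg} in [0, 360), \code{sd_deg}, and
#'   \code{resultant_length} (mean resultant length in [0, 1]).  A zero
#'   resultant yields \code{mean_deg = NA} with a warning.
#' @export
circular_mean_sd <- function(phase_deg, weights = rep(1, length(phase_deg))) {
  stopifnot(length(phase_deg) >= 1, length(weights) == length(phase_deg),
            all(weights >= 0), sum(weights) > 0)
  th <- phase_deg * pi / 180
  res <- sum(weights * exp(1i * th)) / sum(weights)
  if (Mod(res) < 1e-12) {
    warning("zero resultant vector: circular mean undefined")
    return(list(mean_deg = NA_real_, sd_deg = NA_real_, resultant_length = 0))
  }
  mean_deg <- wrap_angle_360(Arg(res) * 180 / pi)
  dev <- wrap_angle(phase_deg - mean_deg)
  sd_deg <- sqrt(sum(weights * dev^2) / sum(weights))
  list(mean_deg = mean_deg, sd_deg = sd_deg, resultant_length = Mod(res))
}

#' Compare two groups of ROI summaries
#'
#' Amplitude: two-sample two-tailed t test (pooled variance).  Phase: a
#' two-sample two-tailed t test on wrapped angular deviations - each group's
#' phases are wrapped around its own circular mean (giving the within-group
#' dispersions) and the tested difference is the wrapped difference of the
#' two circular means (a small-dispersion linearisation of the circular
#' comparison, stable under wraparound); groups with degenerate variance fall
#' back to an exact-equality check.
#'
#' @param group_a,group_b numeric vectors: amplitudes (percent) or phases
#'   (degrees), each of length >= 2.
#' @param measure "amplitude" or "phase".
#' @return list with \code{statistic}, \code{p}, and per-group \code{mean}
#'   and \code{sd} (circular for phase).
#' @export
compare_groups <- function(group_a, group_b, measure = c("amplitude", "phase")) {
  measure <- match.arg(measure)
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (measure == "amplitude") {
    if (sd(group_a) < 1e-12 && sd(group_b) < 1e-12) {
      same <- isTRUE(all.equal(mean(group_a), mean(group_b)))
      return(list(statistic = if (same) 0 else Inf, p = if (same) 1 else 0,
                  mean = c(mean(group_a), mean(group_b)),
                  sd = c(sd(group_a), sd(group_b))))
    }
    tt <- t.test(group_a, group_b, var.equal = TRUE)
    return(list(statistic = unname(tt$statistic), p = tt$p.value,
                mean = c(mean(group_a), mean(group_b)),
                sd = c(sd(group_a), sd(group_b))))
  }
  ca <- circular_mean_sd(group_a)
  cb <- circular_mean_sd(group_b)
  da <- wrap_angle(group_a - ca$mean_deg)
  db <- wrap_angle(group_b - cb$mean_deg)
  diff <- wrap_angle(cb$mean_deg - ca$mean_deg)
  na <- length(group_a); nb <- length(group_b)
  sp2 <- (sum(da^2) + sum(db^2)) / (na + nb - 2)
  if (sp2 < 1e-12) {
    same <- abs(diff) < 1e-9
    return(list(statistic = if (same) 0 else Inf, p = if (same) 1 else 0,
                mean = c(ca$mean_deg, cb$mean_deg), sd = c(ca$sd_deg, cb$sd_deg)))
  }
  tstat <- diff / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(tstat), na + nb - 2)
  list(statistic = tstat, p = p,
       mean = c(ca$mean_deg, cb$mean_deg), sd = c(ca$sd_deg, cb$sd_deg))
}
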
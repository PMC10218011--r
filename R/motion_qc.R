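# framewise displacement, suprathreshold counting, series screening

#' Framewise displacement of a motion trace
#'
#' \deqn{FD(t) = |\Delta dx(t)| + |\Delta dy(t)| + |\Delta dz(t)| +
#'   |\Delta\alpha(t)| + |\Delta\beta(t)| + |\Delta\gamma(t)|}
#' where the translation deltas are in mm and the rotation deltas are
#' converted from degrees to arc length in mm at \code{radius_mm} (default
#' 50 mm, approximating the distance between the head center and the
#' occipital regions of interest in infants).  FD is undefined at the first
#' time point and stored as 0 by convention.
#'
#' @param trace a \code{motion_trace} (or 6-column table) with translations in
#'   mm and rotations in degrees; length >= 2.
#' @param radius_mm head radius used for the degree-to-arc-length conversion.
#' @return an \code{fd_series}: list with \code{fd} (mm, same length as the
#'   trace, first element 0) and \code{radius_mm}.
#' @export
framewise_displacement <- function(trace, radius_mm = 50) {
  trace <- as_motion_trace(trace)
  if (nrow(trace) < 2) stop("FD needs a trace of length >= 2")
  m <- as.matrix(trace)
  d <- abs(diff(m))
  fd <- unname(rowSums(d[, 1:3, drop = FALSE]) +
    radius_mm * rowSums(d[, 4:6, drop = FALSE] * pi / 180))
  structure(list(fd = c(0, fd), radius_mm = radius_mm), class = "fd_series")
}

#' Count suprathreshold framewise displacements
#'
#' Strict inequality: time points with FD > \code{threshold_mm}.
#'
#' @param fd_series an \code{fd_series} or bare numeric FD vector.
#' @param threshold_mm displacement threshold in mm.
#' @return non-negative integer count.
#' @export
count_suprathreshold <- function(fd_series, threshold_mm = 0.5) {
  fd <- if (inherits(fd_series, "fd_series")) fd_series$fd else fd_series
  sum(fd > threshold_mm)
}

#' Screen a run for exclusion or segmentation by head motion
#'
#' A series is excluded when its cumulative displacement range (max minus min
#' of each parameter, translations in mm, rotations as arc length at
#' \code{radius_mm}) exceeds \code{translation_limit_mm} or
#' \code{rotation_limit_mm} with no usable still segment.  When heavy
#' movement (FD > \code{seg_fd_mm}) and stillness are copresent, the run is
#' segmented: the retained intervals are the maximal quiet spans of at least
#' \code{min_segment} time points whose within-span ranges stay inside the
#' limits; spans around the movement are treated downstream as independent
#' shorter series.  Sporadic moderate FD events (0.5-1 mm) are counted by the
#' QC summary but do not by themselves segment a run.
#'
#' @param trace a \code{motion_trace}.
#' @param translation_limit_mm exclusion limit on per-axis translation range.
#' @param rotation_limit_mm exclusion limit on per-axis rotation range,
#'   expressed as arc length in mm at \code{radius_mm}.
#' @param radius_mm head radius for rotation arc length.
#' @param seg_fd_mm FD level marking heavy movement that triggers
#'   segmentation.
#' @param min_segment minimum retained segment length in time points
#'   (default 28 = two full stimulus periods, so period averaging stays
#'   possible).
#' @return a \code{screen_result}: list with \code{verdict} in
#'   \{"keep", "segment", "exclude"\}, \code{intervals} (2-column matrix of
#'   retained index ranges) and \code{reason}.
#' @export
screen_run <- function(trace, translation_limit_mm = 4, rotation_limit_mm = 5,
                       radius_mm = 50, seg_fd_mm = 1, min_segment = 28) {
  trace <- as_motion_trace(trace)
  n <- nrow(trace)
  m <- as.matrix(trace)
  m[, 4:6] <- m[, 4:6] * pi / 180 * radius_mm  # rotations as arc length, mm
  limits <- c(rep(translation_limit_mm, 3), rep(rotation_limit_mm, 3))
  ranges <- apply(m, 2, function(x) diff(range(x)))
  fd <- framewise_displacement(trace, radius_mm)$fd
  quiet <- fd <= seg_fd_mm

  ok_span <- function(iv) {
    sub <- m[iv[1]:iv[2], , drop = FALSE]
    all(apply(sub, 2, function(x) diff(range(x))) <= limits) &&
      (iv[2] - iv[1] + 1) >= min_segment
  }

  if (all(quiet)) {
    if (all(ranges <= limits)) {
      return(structure(list(verdict = "keep",
                            intervals = cbind(start = 1L, end = n),
                            reason = "motion within limits"),
                       class = "screen_result"))
    }
    return(structure(list(verdict = "exclude",
                          intervals = matrix(integer(0), 0, 2,
                                             dimnames = list(NULL, c("start", "end"))),
                          reason = "cumulative head motion exceeds limits with no still segment"),
                     class = "screen_result"))
  }

  runs <- true_runs(quiet)
  keepers <- runs[apply(runs, 1, ok_span), , drop = FALSE]
  if (nrow(keepers) == 0) {
    return(structure(list(verdict = "exclude",
                          intervals = matrix(integer(0), 0, 2,
                                             dimnames = list(NULL, c("start", "end"))),
                          reason = "heavy movement with no usable still segment"),
                     class = "screen_result"))
  }
  colnames(keepers) <- c("start", "end")
  structure(list(verdict = "segment", intervals = keepers,
                 reason = sprintf("movement and stillness copresent; %d still segment(s) retained",
                                  nrow(keepers))),
            class = "screen_result")
}

#' Summarize head motion per group and series
#'
#' One row per group/series combination with, for each of the six rigid-body
#' directions, the mean and SD of the absolute displacement relative to the
#' run start (so a constant trace summarizes to zero), followed by the FD
#' mean and SD and the mean suprathreshold count.  Means are grand means over
#' all time points of all traces in the cell; SDs are between-trace SDs of
#' the per-trace means.
#'
#' @param traces list of \code{motion_trace}.
#' @param group character vector, one group label per trace.
#' @param series character vector, one series label per trace.
#' @param fd_threshold_mm threshold for the suprathreshold count.
#' @param radius_mm head radius for FD.
#' @return data.frame, one row per group x series.
#' @export
summarize_motion <- function(traces, group = rep("all", length(traces)),
                             series = rep("run", length(traces)),
                             fd_threshold_mm = 0.5, radius_mm = 50) {
  stopifnot(length(traces) >= 1, length(group) == length(traces),
            length(series) == length(traces))
  per_trace <- lapply(traces, function(tr) {
    tr <- as_motion_trace(tr)
    disp <- abs(sweep(as.matrix(tr), 2, as.numeric(tr[1, ])))
    fd <- framewise_displacement(tr, radius_mm)$fd
    c(colMeans(disp), fd_mean = mean(fd),
      n_supra = count_suprathreshold(fd, fd_threshold_mm))
  })
  pt <- do.call(rbind, per_trace)
  cells <- unique(data.frame(group = group, series = series,
                             stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- group == cells$group[i] & series == cells$series[i]
    sub <- pt[sel, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- if (sum(sel) > 1) apply(sub, 2, sd) else rep(0, ncol(sub))
    data.frame(
      group = cells$group[i], series = cells$series[i], n_traces = sum(sel),
      tx_mean = mu["dx"], tx_sd = sdv["dx"], ty_mean = mu["dy"], ty_sd = sdv["dy"],
      tz_mean = mu["dz"], tz_sd = sdv["dz"], rx_mean = mu["rx"], rx_sd = sdv["rx"],
      ry_mean = mu["ry"], ry_sd = sdv["ry"], rz_mean = mu["rz"], rz_sd = sdv["rz"],
      fd_mean = mu["fd_mean"], fd_sd = sdv["fd_mean"],
      n_supra_mean = mu["n_supra"], n_supra_sd = sdv["n_supra"],
      row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}
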
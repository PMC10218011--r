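# resting-state ROI-pair connectivity: per-subject matrices, group means,
# aggregate-subject significance, between-group comparison

#' Per-subject 7x7 ROI correlation matrix
#'
#' Pearson correlation at lag 0 between the ROI mean time courses of a
#' resting run, after dummy removal and Fourier high-pass (two cycles).
#' Rows/columns follow the fixed order \code{ROI_ORDER}.  Missing ROIs (NULL
#' entries) yield NA rows/columns so that subjects lacking an ROI are
#' excluded pairwise downstream.
#'
#' @param rest_run a \code{bold_run}.
#' @param rois named list of \code{roi} objects (or voxel-index vectors);
#'   names must match \code{ROI_ORDER}; missing/NULL entries allowed.
#' @param n_cycles high-pass harmonics.
#' @return a \code{connectivity_matrix}: 7x7 symmetric matrix with unit
#'   diagonal and attribute \code{n_timepoints}.
#' @export
roi_corr_matrix <- function(rest_run, rois, n_cycles = 2) {
  stopifnot(inherits(rest_run, "bold_run"))
  if (rest_run$n_retained < 30) stop("retained rest run too short (< 30 points)")
  tcs <- roi_series_matrix(rest_run, rois, n_cycles)
  R <- matrix(NA_real_, 7, 7, dimnames = list(ROI_ORDER, ROI_ORDER))
  ok <- !vapply(seq_len(7), function(i) all(is.na(tcs[, i])), TRUE)
  if (any(ok)) R[ok, ok] <- cor(tcs[, ok, drop = FALSE])
  diag(R)[ok] <- 1
  structure(R, class = c("connectivity_matrix", "matrix"),
            n_timepoints = rest_run$n_retained)
}

# retained-time x 7 matrix of high-passed ROI series (NA column if ROI missing)
roi_series_matrix <- function(run, rois, n_cycles = 2) {
  out <- matrix(NA_real_, run$n_retained, 7)
  colnames(out) <- ROI_ORDER
  for (i in seq_along(ROI_ORDER)) {
    lab <- ROI_ORDER[i]
    r <- rois[[lab]]
    if (is.null(r)) next
    out[, i] <- fourier_highpass(extract_timecourse(run, r), n_cycles)
  }
  out
}

#' Elementwise mean of connectivity matrices
#'
#' @param matrices list of \code{connectivity_matrix}; cells missing in a
#'   subject (NA) are averaged over the available subjects.
#' @return a \code{connectivity_matrix} of means.
#' @export
group_mean_matrix <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  arr <- simplify2array(lapply(matrices, unclass))
  M <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  M[is.nan(M)] <- NA_real_
  dimnames(M) <- list(ROI_ORDER, ROI_ORDER)
  structure(M, class = c("connectivity_matrix", "matrix"),
            n_timepoints = NA_integer_)
}

#' Aggregate-subject correlation and significance
#'
#' Each subject's ROI series is z-scored and the series are concatenated into
#' one "aggregate subject" per ROI; the Pearson correlation of the aggregate
#' series equals (for equal-length runs) the mean of the per-subject
#' correlations, and its r-to-t transform with df = total points - 2 gives
#' each cell's p value.  Constant series are excluded with a warning.
#'
#' @param rest_runs list of \code{bold_run}, one per subject (>= 2).
#' @param rois_by_subject list (one per subject) of named ROI lists as in
#'   \code{\link{roi_corr_matrix}}; a single shared list is recycled.
#' @param n_cycles high-pass harmonics.
#' @return list with \code{r} (aggregate 7x7 correlation), \code{p} (7x7 p
#'   values) and \code{n_points} per ROI pair.
#' @export
aggregate_significance <- function(rest_runs, rois_by_subject, n_cycles = 2) {
  stopifnot(length(rest_runs) >= 2)
  if (!is.null(names(rois_by_subject)) &&
      all(names(rois_by_subject) %in% ROI_ORDER)) {
    rois_by_subject <- rep(list(rois_by_subject), length(rest_runs))
  }
  stopifnot(length(rois_by_subject) == length(rest_runs))
  zs <- lapply(seq_along(rest_runs), function(s) {
    m <- roi_series_matrix(rest_runs[[s]], rois_by_subject[[s]], n_cycles)
    apply(m, 2, function(x) {
      if (all(is.na(x))) return(x)
      if (sd(x) < 1e-12) {
        warning("constant ROI series excluded from the aggregate subject")
        return(rep(NA_real_, length(x)))
      }
      (x - mean(x)) / sd(x)
    })
  })
  agg <- do.call(rbind, zs)
  R <- matrix(NA_real_, 7, 7, dimnames = list(ROI_ORDER, ROI_ORDER))
  P <- R
  N <- matrix(NA_integer_, 7, 7, dimnames = list(ROI_ORDER, ROI_ORDER))
  for (i in 1:7) for (j in 1:7) {
    pair <- complete.cases(agg[, c(i, j)])
    n <- sum(pair)
    if (n < 10) next
    r <- cor(agg[pair, i], agg[pair, j])
    R[i, j] <- r
    N[i, j] <- n
    if (i == j) { P[i, j] <- 0; next }
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    P[i, j] <- 2 * pt(-abs(tstat), n - 2)
  }
  list(r = R, p = P, n_points = N)
}

#' Between-group comparison of connectivity matrices
#'
#' Per-cell two-tailed two-sample t test of the subjects' correlations,
#' Fisher-z transformed by default for variance stabilisation (\code{scale =
#' "raw"} compares untransformed r).  Cells with fewer than 2 subjects per
#' group are NA.  Significance flags at 0.05 and 0.01 are reported on the
#' upper triangle.
#'
#' @param group_a,group_b lists of \code{connectivity_matrix}.
#' @param scale "fisher" or "raw".
#' @return list with \code{p} (7x7), \code{t} (7x7) and \code{flags}
#'   (7x7 character: "", "*" p<=0.05, "**" p<=0.01; upper triangle only).
#' @export
compare_matrices <- function(group_a, group_b, scale = c("fisher", "raw")) {
  scale <- match.arg(scale)
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  xf <- function(m) {
    v <- unclass(m)
    if (scale == "fisher") atanh(pmin(pmax(v, -1 + 1e-12), 1 - 1e-12)) else v
  }
  A <- simplify2array(lapply(group_a, xf))
  B <- simplify2array(lapply(group_b, xf))
  P <- matrix(NA_real_, 7, 7, dimnames = list(ROI_ORDER, ROI_ORDER))
  Tm <- P
  for (i in 1:7) for (j in 1:7) {
    if (i == j) next
    a <- A[i, j, ]; a <- a[is.finite(a)]
    b <- B[i, j, ]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) next
    if (sd(a) < 1e-12 && sd(b) < 1e-12) {
      same <- isTRUE(all.equal(mean(a), mean(b)))
      P[i, j] <- if (same) 1 else 0
      Tm[i, j] <- if (same) 0 else Inf
      next
    }
    tt <- t.test(a, b, var.equal = TRUE)
    P[i, j] <- tt$p.value
    Tm[i, j] <- unname(tt$statistic)
  }
  flags <- matrix("", 7, 7, dimnames = list(ROI_ORDER, ROI_ORDER))
  up <- upper.tri(flags)
  flags[up & !is.na(P) & P <= 0.05] <- "*"
  flags[up & !is.na(P) & P <= 0.01] <- "**"
  list(p = P, t = Tm, flags = flags)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("7x7 ROI connectivity matrix (Pearson r):\n")
  print(round(unclass(x), 2))
  invisible(x)
}
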
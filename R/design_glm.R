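# design matrix construction and voxelwise OLS GLM

#' Build the GLM design matrix
#'
#' Columns: the regressor of interest (condition boxcar convolved with the
#' HRF, coded 1 during C1 and 0 during C2 so its weight is the C1 minus C2
#' response), six motion nuisance regressors (demeaned), Fourier high-pass
#' sine/cosine pairs up to \code{n_harmonics} cycles per run, and a constant.
#' Constant (all-zero after demeaning) motion columns are dropped with a
#' warning.  Time points are the retained (post-dummy) points.
#'
#' @param schedule a \code{condition_schedule}.
#' @param hrf an \code{hrf}; default the calibrated canonical HRF.
#' @param motion_trace motion parameters for the retained time points
#'   (dummies already dropped), or NULL to omit motion regressors.
#' @param n_harmonics number of Fourier high-pass harmonics (default 2,
#'   the "two cycles" GLM-Fourier high-pass).
#' @param retained optional integer vector of retained time-point indices
#'   (relative to the retained run) when a run was segmented.
#' @return a \code{design_matrix}: list with the matrix \code{X}, the column
#'   names, the interest column name ("task"), the schedule, and
#'   \code{retained}.
#' @export
build_design <- function(schedule, hrf = default_hrf(), motion_trace = NULL,
                         n_harmonics = 2, retained = NULL) {
  stopifnot(inherits(schedule, "condition_schedule"))
  n <- schedule$n_retained
  task <- convolve_hrf(boxcar_regressor(schedule), hrf)
  X <- cbind(task = task)

  if (!is.null(motion_trace)) {
    mt <- as.matrix(as_motion_trace(motion_trace))
    if (nrow(mt) != n) stop("motion trace length (", nrow(mt),
                            ") does not match retained run length (", n, ")")
    mt <- sweep(mt, 2, colMeans(mt))
    colnames(mt) <- paste0("motion_", c("dx", "dy", "dz", "rx", "ry", "rz"))
    zero <- apply(mt, 2, function(x) all(abs(x) < 1e-12))
    if (any(zero)) {
      warning("dropping constant motion regressor(s): ",
              paste(colnames(mt)[zero], collapse = ", "))
      mt <- mt[, !zero, drop = FALSE]
    }
    if (ncol(mt)) X <- cbind(X, mt)
  }

  tt <- seq_len(n)
  for (k in seq_len(n_harmonics)) {
    X <- cbind(X, sin(2 * pi * k * tt / n), cos(2 * pi * k * tt / n))
    colnames(X)[(ncol(X) - 1):ncol(X)] <- paste0(c("hp_sin_", "hp_cos_"), k)
  }
  X <- cbind(X, constant = 1)

  if (!is.null(retained)) {
    stopifnot(all(retained >= 1), all(retained <= n))
    X <- X[retained, , drop = FALSE]
  } else {
    retained <- seq_len(n)
  }

  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  structure(list(X = X, columns = colnames(X), interest = "task",
                 schedule = schedule, retained = retained),
            class = "design_matrix")
}

#' Fit the voxelwise GLM and produce stat maps
#'
#' Ordinary least squares per voxel (no prewhitening, matching the original
#' analysis), t = contrast estimate / SE with df = rows - rank, two-sided p,
#' and a standard-normal equivalent Z score (sign-preserving).  Betas are
#' rescaled to percent signal change using the fitted constant column as the
#' voxel baseline, so a noiseless simulated amplitude is recovered exactly.
#' Voxels with (numerically) zero residual variance are flagged with p = 0
#' and infinite t rather than failing.
#'
#' @param run a \code{bold_run} (dummies are dropped internally) or a
#'   retained time x voxel matrix.
#' @param design a \code{design_matrix}.
#' @param contrast name of the design column to test (default the interest
#'   regressor).
#' @return a \code{stat_map}: list with vectors \code{beta} (percent),
#'   \code{t}, \code{p}, \code{z}, plus \code{df}, \code{dim} (NULL for
#'   matrix input).
#' @export
fit_glm <- function(run, design, contrast = "task") {
  stopifnot(inherits(design, "design_matrix"))
  if (inherits(run, "bold_run")) {
    Y <- run_matrix(run)[design$retained, , drop = FALSE]
    dim3 <- run$dim
  } else {
    Y <- as.matrix(run)[design$retained, , drop = FALSE]
    dim3 <- NULL
  }
  X <- design$X
  if (nrow(Y) != nrow(X)) stop("run retained length does not match design rows")
  ci <- match(contrast, colnames(X))
  if (is.na(ci)) stop("no design column named '", contrast, "'")

  qrx <- qr(X)
  coefs <- qr.coef(qrx, Y)                      # p x voxels
  res <- Y - X %*% coefs
  df <- nrow(X) - qrx$rank
  sigma2 <- colSums(res^2) / df
  xtxinv <- chol2inv(qr.R(qrx))
  se <- sqrt(pmax(sigma2 * xtxinv[ci, ci], 0))
  beta_raw <- coefs[ci, ]
  baseline <- coefs[match("constant", colnames(X)), ]

  scale_ok <- is.finite(baseline) & baseline > 0
  beta <- ifelse(scale_ok, 100 * beta_raw / baseline, NA_real_)

  noiseless <- sigma2 <= 1e-12 * pmax(colMeans(Y^2), .Machine$double.eps)
  # a noiseless voxel with a real effect gets p = 0; a noiseless voxel whose
  # effect is numerically zero is a flat voxel, not an infinitely strong one
  null_beta <- abs(beta_raw) <= 1e-8 * sqrt(pmax(colMeans(Y^2), .Machine$double.eps))
  tstat <- ifelse(noiseless, ifelse(null_beta, 0, sign(beta_raw) * Inf),
                  beta_raw / se)
  p <- ifelse(noiseless, ifelse(null_beta, 1, 0), 2 * pt(-abs(beta_raw / se), df))
  z <- t_to_z(tstat, df)

  structure(list(beta = beta, beta_raw = beta_raw, t = tstat, p = p, z = z,
                 df = df, dim = dim3, contrast = contrast),
            class = "stat_map")
}

#' Convert t statistics to standard-normal equivalent Z scores
#'
#' Sign-preserving and monotone in |t|; computed on the log scale so large
#' statistics do not underflow.
#'
#' @param t t statistics.
#' @param df degrees of freedom.
#' @return Z scores.
#' @export
t_to_z <- function(t, df) {
  z <- sign(t) * qnorm(pt(abs(t), df, lower.tail = FALSE, log.p = TRUE),
                       lower.tail = FALSE, log.p = TRUE)
  z[is.infinite(t)] <- sign(t[is.infinite(t)]) * Inf
  z[is.na(t)] <- NA_real_
  z
}

#' Threshold a stat map
#'
#' Inclusive threshold: voxels with p <= \code{p_threshold} and the requested
#' effect sign.
#'
#' @param statmap a \code{stat_map}.
#' @param p_threshold p-value threshold.
#' @param sign one of "pos", "neg", "both".
#' @return integer vector of voxel indices.
#' @export
threshold_map <- function(statmap, p_threshold, sign = c("both", "pos", "neg")) {
  sign <- match.arg(sign)
  keep <- statmap$p <= p_threshold
  keep[is.na(keep)] <- FALSE
  if (sign == "pos") keep <- keep & statmap$t > 0
  if (sign == "neg") keep <- keep & statmap$t < 0
  which(keep)
}

#' Fourier high-pass filter a series
#'
#' Removes the constant and the sine/cosine pairs up to \code{n_cycles}
#' cycles per series by least-squares projection (the GLM-Fourier high-pass),
#' returning the residuals.
#'
#' @param x numeric vector or time x voxel matrix.
#' @param n_cycles number of cycles per run to remove (default 2).
#' @return filtered series, same shape as the input.
#' @export
fourier_highpass <- function(x, n_cycles = 2) {
  v <- is.null(dim(x))
  m <- if (v) matrix(x, ncol = 1) else as.matrix(x)
  n <- nrow(m)
  tt <- seq_len(n)
  B <- cbind(1, do.call(cbind, lapply(seq_len(n_cycles), function(k) {
    cbind(sin(2 * pi * k * tt / n), cos(2 * pi * k * tt / n))
  })))
  res <- m - B %*% qr.coef(qr(B), m)
  if (v) drop(res) else res
}

# number of regressors removed by fourier_highpass (for df accounting)
highpass_df <- function(n_cycles = 2) 1L + 2L * n_cycles
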
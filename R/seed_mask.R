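# V1 seed detection, lagged seed-correlation maps, union mask, ROI labeling

#' Construct an ROI object
#'
#' @param label ROI label.
#' @param hemisphere "L", "R" or "midline".
#' @param voxels linear voxel indices.
#' @param dim grid dimensions.
#' @param vox_mm voxel size (mm).
#' @param peak_z peak |Z| inside the ROI.
#' @param sign sign of the defining effect (+1 / -1 / NA).
#' @return object of class \code{roi} (with voxel count \code{n} and center
#'   of mass \code{com_mm}, origin at the volume center).
#' @export
new_roi <- function(label, hemisphere, voxels, dim, vox_mm = 3,
                    peak_z = NA_real_, sign = NA_real_) {
  stopifnot(length(voxels) >= 1, all(voxels >= 1), all(voxels <= prod(dim)))
  structure(list(label = label, hemisphere = hemisphere,
                 voxels = sort(as.integer(voxels)), dim = dim,
                 vox_mm = vox_mm, n = length(voxels),
                 com_mm = com_mm(voxels, dim, vox_mm),
                 peak_z = peak_z, sign = sign),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("ROI %s (%s): %d voxels, com (%.1f, %.1f, %.1f) mm, peak Z %.2f\n",
              x$label, x$hemisphere, x$n,
              x$com_mm[1], x$com_mm[2], x$com_mm[3], x$peak_z))
  invisible(x)
}

#' Define the V1 seed from the stimulus-vs-blank stat map
#'
#' Voxels significant at \code{p_threshold} (positive responses) are
#' intersected with the calcarine prior box; the largest connected
#' component(s) (6-neighbour adjacency; components tied with the largest are
#' all kept, covering the bilateral-calcarine case) form the seed.
#'
#' @param statmap stat map of the stimulus-vs-blank GLM.
#' @param calcarine_prior 3x2 matrix of voxel bounds, or an integer vector of
#'   prior voxel indices.
#' @param p_threshold significance threshold (default 0.01).
#' @param vox_mm voxel size.
#' @return an \code{roi} labeled "V1".
#' @export
define_v1_seed <- function(statmap, calcarine_prior, p_threshold = 0.01,
                           vox_mm = 3) {
  stopifnot(inherits(statmap, "stat_map"), !is.null(statmap$dim))
  pv <- if (is.matrix(calcarine_prior)) {
    prior_voxels(calcarine_prior, statmap$dim)
  } else as.integer(calcarine_prior)
  if (length(pv) == 0) stop("calcarine prior region is empty")
  cand <- intersect(threshold_map(statmap, p_threshold, "pos"), pv)
  if (length(cand) == 0) {
    stop("no suprathreshold voxels in the calcarine prior; ",
         "review the threshold (", p_threshold, ") or the prior region")
  }
  comps <- connected_components(cand, statmap$dim)
  nmax <- length(comps[[1]])
  vox <- sort(unlist(comps[vapply(comps, length, 1L) == nmax]))
  new_roi("V1", "midline", vox, statmap$dim, vox_mm,
          peak_z = max(statmap$z[vox]), sign = 1)
}

#' Lagged correlation map of a seed time course against all voxels
#'
#' Both the seed and every voxel series are Fourier high-passed (two cycles),
#' then Pearson-correlated at each temporal lag (positive lag = voxel series
#' delayed behind the seed).  p values use the r-to-t transform with
#' df = overlap - 2 - (high-pass regressors), the partial-correlation degrees
#' of freedom.  Constant voxels get r = 0, p = 1.
#'
#' @param run a \code{bold_run} (dummies dropped internally).
#' @param seed_timecourse seed series on the retained time points.
#' @param lags_s temporal delays in seconds; each must be a multiple of the TR.
#' @param n_cycles high-pass harmonics removed before correlating.
#' @return a \code{lag_corr_map}: list with per-lag matrices \code{r} and
#'   \code{p} (voxels x lags), \code{lags_s}, \code{n_eff}.
#' @export
lagged_correlation_map <- function(run, seed_timecourse, lags_s = c(0, 3),
                                   n_cycles = 2) {
  stopifnot(inherits(run, "bold_run"))
  Y <- run_matrix(run)
  n <- nrow(Y)
  stopifnot(length(seed_timecourse) == n)
  lags <- lags_s / run$tr_s
  if (any(abs(lags - round(lags)) > 1e-9)) stop("each lag must be a multiple of the TR")
  lags <- as.integer(round(lags))

  Yf <- fourier_highpass(Y, n_cycles)
  sf <- fourier_highpass(seed_timecourse, n_cycles)
  q <- highpass_df(n_cycles)

  rmat <- matrix(NA_real_, ncol(Y), length(lags))
  pmat <- matrix(NA_real_, ncol(Y), length(lags))
  neff <- integer(length(lags))
  for (j in seq_along(lags)) {
    L <- lags[j]
    if (n - L < 10) stop("overlap after shifting must be at least 10 samples")
    s <- sf[seq_len(n - L)]
    V <- Yf[(1 + L):n, , drop = FALSE]
    sdv <- apply(V, 2, sd)
    const <- sdv < 1e-12 | sd(s) < 1e-12
    r <- rep(0, ncol(V))
    r[!const] <- drop(cor(s, V[, !const, drop = FALSE]))
    df <- (n - L) - 2L - q
    tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df)
    p[abs(r) >= 1] <- 0
    p[const] <- 1
    r[const] <- 0
    rmat[, j] <- r
    pmat[, j] <- p
    neff[j] <- n - L
  }
  structure(list(r = rmat, p = pmat, lags_s = lags_s, n_eff = neff,
                 dim = run$dim), class = "lag_corr_map")
}

#' Union mask of the lagged correlation maps
#'
#' Voxels significant (p <= threshold) at either lag.  By default both
#' correlation signs are admitted, so regions whose stimulus response is
#' anticorrelated with the seed (e.g. PIVC under visual stimulation) stay in
#' the mask; set \code{sign = "pos"} for a strictly positive-connectivity
#' mask.
#'
#' @param map a \code{lag_corr_map}.
#' @param p_threshold significance threshold (default 0.05).
#' @param sign "both", "pos" or "neg".
#' @return integer vector of voxel indices.
#' @export
union_mask <- function(map, p_threshold = 0.05, sign = c("both", "pos", "neg")) {
  sign <- match.arg(sign)
  keep <- map$p <= p_threshold
  if (sign == "pos") keep <- keep & map$r > 0
  if (sign == "neg") keep <- keep & map$r < 0
  which(rowSums(keep, na.rm = TRUE) > 0)
}

#' Label ROIs inside the mask from the coherent-vs-random stat map
#'
#' Connected suprathreshold components (both signs; 6-neighbour adjacency)
#' inside the mask are assigned to the nearest prior region (by distance from
#' the component's center of mass to the prior center, within
#' \code{max_dist_vox}); components matching no prior are returned labeled
#' "unassigned".  When several components share a label, the focus kept for
#' that area is the largest one - smaller same-label satellites are almost
#' always suprathreshold noise and would dilute the ROI time course.
#'
#' @param statmap stat map of the within-mask GLM.
#' @param mask integer vector of mask voxel indices.
#' @param scene_priors either a \code{scene_spec} or a list of priors, each a
#'   list with \code{label}, \code{hemisphere}, \code{center} (voxel coords).
#' @param p_threshold significance threshold (default 0.05).
#' @param max_dist_vox maximum center-to-center assignment distance in voxels.
#' @param vox_mm voxel size.
#' @return list of \code{roi} objects.
#' @export
label_rois <- function(statmap, mask, scene_priors, p_threshold = 0.05,
                       max_dist_vox = 4, vox_mm = 3) {
  stopifnot(inherits(statmap, "stat_map"), !is.null(statmap$dim))
  if (length(mask) == 0) stop("mask is empty")
  priors <- if (inherits(scene_priors, "scene_spec")) scene_priors$rois else scene_priors
  # foci are sign-coherent: positive and negative responses cluster separately
  sig_pos <- intersect(threshold_map(statmap, p_threshold, "pos"), mask)
  sig_neg <- intersect(threshold_map(statmap, p_threshold, "neg"), mask)
  if (length(sig_pos) + length(sig_neg) == 0) return(list())
  comps <- c(connected_components(sig_pos, statmap$dim),
             connected_components(sig_neg, statmap$dim))

  centers <- do.call(rbind, lapply(priors, `[[`, "center"))
  assigned <- list()
  for (comp in comps) {
    ijk <- lin_to_ijk(comp, statmap$dim)
    cm <- colMeans(matrix(ijk, ncol = 3))
    d <- sqrt(rowSums(sweep(centers, 2, cm)^2))
    j <- which.min(d)
    lab <- if (d[j] <= max_dist_vox) priors[[j]]$label else "unassigned"
    assigned[[length(assigned) + 1L]] <- list(label = lab, voxels = comp)
  }
  labs <- vapply(assigned, `[[`, "", "label")
  out <- list()
  for (lab in unique(labs)) {
    cand <- assigned[labs == lab]
    vox <- if (lab == "unassigned") {
      sort(unlist(lapply(cand, `[[`, "voxels")))   # reported jointly
    } else {
      sizes <- vapply(cand, function(a) length(a$voxels), 1L)
      cand[[which.max(sizes)]]$voxels
    }
    hemi <- if (lab == "unassigned") NA_character_ else {
      priors[[which(vapply(priors, `[[`, "", "label") == lab)]]$hemisphere
    }
    pk <- vox[which.max(abs(statmap$z[vox]))]
    out[[length(out) + 1L]] <- new_roi(
      lab, hemi, vox, statmap$dim, vox_mm,
      peak_z = statmap$z[pk], sign = sign(statmap$t[pk]))
  }
  if (any(labs == "unassigned")) {
    message(sum(labs == "unassigned"),
            " component(s) overlapped no prior region; labeled 'unassigned'")
  }
  out
}

#' ROI table in the standard report layout
#'
#' One row per ROI: label, hemisphere, voxel count, center of mass (mm, x/y/z
#' from the volume center) and peak Z.
#'
#' @param rois list of \code{roi}.
#' @return data.frame.
#' @export
roi_table <- function(rois) {
  do.call(rbind, lapply(rois, function(r) {
    data.frame(label = r$label, hemisphere = r$hemisphere, n = r$n,
               x_mm = round(r$com_mm[1], 1), y_mm = round(r$com_mm[2], 1),
               z_mm = round(r$com_mm[3], 1),
               peak_z = round(r$peak_z, 2), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}
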
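# end-to-end orchestration of the stimulus and resting-state pipelines

#' Run the full stimulus pipeline for one subject
#'
#' Stages: dummy drop -> motion screening -> GLM of the stimulus-vs-blank run
#' -> V1 seed (p <= seed_p inside the calcarine prior) -> lag-0 and lag-1-TR
#' seed correlation maps -> union mask -> GLM of the coherent-vs-random run
#' inside the mask -> ROI labeling (p <= map_p, both signs) -> ROI time
#' courses -> period averaging, windowed mean, spectral SNR/phase.  The V1
#' ROI reported is the seed itself (the labeling stage covers the remaining
#' areas).  A subject whose runs fail screening is returned with status
#' "excluded" rather than erroring, so cohort loops continue.
#'
#' @param blank list with elements \code{run} (a \code{bold_run}) and
#'   \code{motion} (a \code{motion_trace}) for the stimulus-vs-blank series.
#' @param random same, for the coherent-vs-random series.
#' @param priors a \code{scene_spec} (synthetic mode) or prior list as in
#'   \code{\link{label_rois}}; must also carry the calcarine prior when a
#'   scene is not supplied.
#' @param config configuration list, see \code{\link{default_config}}.
#' @param hrf HRF used for the design; default the calibrated canonical HRF.
#' @return list with \code{status}, \code{seed}, \code{mask}, \code{rois},
#'   \code{roi_stats} (one row per ROI: size, position, peak Z, amplitude,
#'   windowed mean, SNR, phase, spectral p, good periods) and the screening
#'   results.
#' @export
run_stimulus_pipeline <- function(blank, random, priors,
                                  config = default_config(),
                                  hrf = default_hrf()) {
  stopifnot(inherits(blank$run, "bold_run"), inherits(random$run, "bold_run"))
  sched_b <- blank$run$schedule
  sched_r <- random$run$schedule
  stopifnot(!is.null(sched_b), !is.null(sched_r))

  retained_trace <- function(x) {
    tr <- as_motion_trace(x$motion)
    tr[(x$run$n_dummy + 1):nrow(tr), , drop = FALSE]
  }
  scr_b <- screen_run(retained_trace(blank),
                      translation_limit_mm = config$translation_limit_mm,
                      rotation_limit_mm = config$rotation_limit_mm,
                      radius_mm = config$head_radius_mm,
                      seg_fd_mm = config$seg_fd_mm,
                      min_segment = config$min_segment)
  scr_r <- screen_run(retained_trace(random),
                      translation_limit_mm = config$translation_limit_mm,
                      rotation_limit_mm = config$rotation_limit_mm,
                      radius_mm = config$head_radius_mm,
                      seg_fd_mm = config$seg_fd_mm,
                      min_segment = config$min_segment)
  if (scr_b$verdict == "exclude" || scr_r$verdict == "exclude") {
    return(list(status = "excluded",
                reason = paste("motion screening:",
                               if (scr_b$verdict == "exclude") scr_b$reason else scr_r$reason),
                screen_blank = scr_b, screen_random = scr_r))
  }
  ret_idx <- function(scr, n) {
    if (scr$verdict == "keep") seq_len(n) else {
      sort(unlist(apply(scr$intervals, 1, function(iv) iv[1]:iv[2], simplify = FALSE)))
    }
  }
  idx_b <- ret_idx(scr_b, sched_b$n_retained)
  idx_r <- ret_idx(scr_r, sched_r$n_retained)

  # stage 1: stimulus-vs-blank GLM and the V1 seed
  des_b <- build_design(sched_b, hrf, as_motion_trace(retained_trace(blank)),
                        n_harmonics = config$n_harmonics, retained = idx_b)
  map_blank <- fit_glm(blank$run, des_b)
  # `priors` is a scene_spec or a list(rois = <prior list>, calcarine_prior = <3x2 bounds>)
  prior_list <- if (inherits(priors, "scene_spec")) priors else priors$rois
  seed <- define_v1_seed(map_blank, priors$calcarine_prior, p_threshold = config$seed_p,
                         vox_mm = blank$run$vox_mm)

  # stage 2: lagged seed-correlation maps and their union mask
  seed_tc <- extract_timecourse(blank$run, seed)
  lagmap <- lagged_correlation_map(blank$run, seed_tc, lags_s = config$lags_s,
                                   n_cycles = config$n_harmonics)
  mask <- union_mask(lagmap, p_threshold = config$map_p, sign = config$mask_sign)

  # stage 3: coherent-vs-random GLM inside the mask, then labeling
  des_r <- build_design(sched_r, hrf, as_motion_trace(retained_trace(random)),
                        n_harmonics = config$n_harmonics, retained = idx_r)
  Y_mask <- run_matrix(random$run)[, mask, drop = FALSE]
  sub <- fit_glm(Y_mask, des_r)
  nvox <- prod(random$run$dim)
  map_random <- structure(list(
    beta = scatter(sub$beta, mask, nvox, NA_real_),
    beta_raw = scatter(sub$beta_raw, mask, nvox, NA_real_),
    t = scatter(sub$t, mask, nvox, 0),
    p = scatter(sub$p, mask, nvox, 1),
    z = scatter(sub$z, mask, nvox, 0),
    df = sub$df, dim = random$run$dim, contrast = sub$contrast),
    class = "stat_map")
  rois <- label_rois(map_random, mask, prior_list, p_threshold = config$map_p,
                     max_dist_vox = config$max_label_dist_vox,
                     vox_mm = random$run$vox_mm)
  rois <- Filter(function(r) r$label != "V1", rois)
  rois <- c(rois, list(seed))

  # stage 4: ROI time courses, period averages, spectral summaries
  stats <- lapply(rois, function(r) {
    tc <- extract_timecourse(random$run, r)
    sp <- split_periods(tc, sched_r, if (scr_r$verdict == "keep") NULL else scr_r)
    pa <- period_average(sp)
    amp <- timecourse_amplitude(tc, des_r)
    spec <- if (length(sp$good) >= 2) {
      gtc <- as.numeric(t(sp$periods[sp$good, , drop = FALSE]))
      spectral_summary(gtc, length(sp$good), sched_r$period_len)
    } else list(snr = NA_real_, phase_deg = NA_real_, p = NA_real_)
    data.frame(label = r$label, hemisphere = r$hemisphere, n = r$n,
               x_mm = r$com_mm[1], y_mm = r$com_mm[2], z_mm = r$com_mm[3],
               peak_z = r$peak_z, amplitude_pct = amp,
               mean_response_pct = mean_response(pa, config$window_trs),
               snr = spec$snr, phase_deg = spec$phase_deg,
               p_spectral = spec$p, n_good_periods = length(sp$good),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  list(status = "ok", seed = seed, mask = mask, rois = rois,
       roi_stats = do.call(rbind, stats), lagmap = lagmap,
       map_blank = map_blank, map_random = map_random,
       screen_blank = scr_b, screen_random = scr_r)
}

scatter <- function(values, idx, n, fill) {
  out <- rep(fill, n)
  out[idx] <- values
  out
}

# GLM amplitude (percent) of a percent time course: weight of the task
# regressor, fitted on the screened time points of the design
timecourse_amplitude <- function(tc_pct, design) {
  y <- tc_pct[design$retained]
  qr.coef(qr(design$X), y)[match("task", colnames(design$X))]
}

#' Run the resting-state pipeline over a cohort
#'
#' Computes the per-subject 7x7 matrices, per-group mean matrices and
#' aggregate-subject significance, and (when both groups have >= 2 subjects)
#' the between-group two-tailed t test per cell; otherwise the comparison is
#' skipped with a warning.
#'
#' @param rest_runs list of \code{bold_run}, one per subject.
#' @param rois_by_subject per-subject named ROI lists (a single shared list
#'   is recycled).
#' @param groups character vector of group labels, one per subject.
#' @param config configuration list.
#' @return list with \code{subject_matrices}, \code{group_means},
#'   \code{aggregate} (per group), and \code{comparison} (NULL if skipped).
#' @export
run_rest_pipeline <- function(rest_runs, rois_by_subject,
                              groups = rep("all", length(rest_runs)),
                              config = default_config()) {
  stopifnot(length(rest_runs) >= 1, length(groups) == length(rest_runs))
  shared <- !is.null(names(rois_by_subject)) &&
    all(names(rois_by_subject) %in% ROI_ORDER)
  get_rois <- function(s) if (shared) rois_by_subject else rois_by_subject[[s]]

  mats <- lapply(seq_along(rest_runs), function(s) {
    roi_corr_matrix(rest_runs[[s]], get_rois(s), n_cycles = config$n_harmonics)
  })
  glabs <- unique(groups)
  means <- lapply(glabs, function(g) group_mean_matrix(mats[groups == g]))
  names(means) <- glabs
  aggr <- lapply(glabs, function(g) {
    sel <- which(groups == g)
    if (length(sel) < 2) return(NULL)
    aggregate_significance(rest_runs[sel],
                           if (shared) rois_by_subject else rois_by_subject[sel],
                           n_cycles = config$n_harmonics)
  })
  names(aggr) <- glabs

  comparison <- NULL
  if (length(glabs) == 2 && all(table(factor(groups, glabs)) >= 2)) {
    comparison <- compare_matrices(mats[groups == glabs[1]],
                                   mats[groups == glabs[2]])
  } else if (length(glabs) == 2) {
    warning("fewer than 2 subjects in a group; between-group comparison skipped")
  }
  list(subject_matrices = mats, group_means = means, aggregate = aggr,
       comparison = comparison, groups = groups)
}
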
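# synthetic cortical scene: ROI layout, amplitudes, priors

#' The fixed ROI order used for connectivity matrices
#'
#' 1 = MT+ R, 2 = MT+ L, 3 = V1, 4 = V6 R, 5 = V6 L, 6 = PIVC R, 7 = PIVC L.
#' @export
ROI_ORDER <- c("MT+ R", "MT+ L", "V1", "V6 R", "V6 L", "PIVC R", "PIVC L")

#' Specify one ROI of the synthetic scene
#'
#' @param label ROI label, one of \code{ROI_ORDER}.
#' @param center voxel coordinate (length 3) of the sphere center.
#' @param radius sphere radius in voxels.
#' @param amp_c1c2 percent-signal-change amplitude for the C1 minus C2
#'   (coherent vs random motion) contrast; may be negative (PIVC responds
#'   more to random than to coherent motion).
#' @param amp_blank percent amplitude for the stimulus vs blank contrast.
#' @param delay_s extra hemodynamic delay in seconds beyond the canonical HRF.
#' @return a list describing the ROI.
#' @export
roi_spec <- function(label, center, radius, amp_c1c2, amp_blank, delay_s = 0) {
  stopifnot(label %in% ROI_ORDER, length(center) == 3, radius >= 0,
            is.finite(amp_c1c2), is.finite(amp_blank))
  hemi <- if (grepl(" L$", label)) "L" else if (grepl(" R$", label)) "R" else "midline"
  list(label = label, hemisphere = hemi, center = center, radius = radius,
       amp_c1c2 = amp_c1c2, amp_blank = amp_blank, delay_s = delay_s)
}

#' Assemble a synthetic cortical scene
#'
#' @param grid 3-axis grid shape in voxels.
#' @param vox_mm isotropic voxel size (mm).
#' @param baseline baseline signal intensity (arbitrary scanner units).
#' @param rois list of \code{roi_spec} entries; must lie inside the grid and
#'   be pairwise disjoint.
#' @param calcarine_prior 3x2 matrix of (min, max) voxel bounds per axis,
#'   marking the "V1 territory" searched for the seed.
#' @return an object of class \code{scene_spec} with a per-voxel membership
#'   map (0 = background, i = index into \code{rois}).
#' @export
scene_spec <- function(grid = c(24, 24, 12), vox_mm = 3, baseline = 1000,
                       rois = default_rois(), calcarine_prior = default_calcarine_prior()) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3, all(grid > 0), vox_mm > 0, baseline > 0)
  membership <- integer(prod(grid))
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    if (any(r$center - r$radius < 1) || any(r$center + r$radius > grid)) {
      stop("ROI '", r$label, "' does not lie inside the grid")
    }
    vox <- sphere_voxels(r$center, r$radius, grid)
    if (any(membership[vox] != 0L)) {
      stop("ROI voxel sets are not disjoint (", r$label, ")")
    }
    membership[vox] <- i
  }
  stopifnot(is.matrix(calcarine_prior), dim(calcarine_prior) == c(3, 2))
  structure(list(grid = grid, vox_mm = vox_mm, baseline = baseline,
                 rois = rois, membership = membership,
                 calcarine_prior = calcarine_prior),
            class = "scene_spec")
}

#' Default ROI layout
#'
#' Seven spherical ROIs on the 24 x 24 x 12 grid: bilateral MT+, V6 and PIVC
#' plus a midline V1, with percent amplitudes in the 0.2-0.6 range observed
#' for these areas (PIVC negative for coherent-vs-random and for
#' stimulus-vs-blank; V1 only weakly selective for coherent vs random but
#' responding strongly to stimulation vs blank).
#'
#' @param radius sphere radius in voxels.
#' @return list of \code{roi_spec}.
#' @export
default_rois <- function(radius = 2) {
  list(
    roi_spec("MT+ L",  c(5, 10, 6),  radius, amp_c1c2 =  0.60, amp_blank =  0.30),
    roi_spec("MT+ R",  c(20, 10, 6), radius, amp_c1c2 =  0.60, amp_blank =  0.30),
    roi_spec("V6 L",   c(9, 9, 10),  radius, amp_c1c2 =  0.50, amp_blank =  0.25),
    roi_spec("V6 R",   c(16, 9, 10), radius, amp_c1c2 =  0.50, amp_blank =  0.25),
    roi_spec("PIVC L", c(4, 16, 5),  radius, amp_c1c2 = -0.30, amp_blank = -0.20),
    roi_spec("PIVC R", c(21, 16, 5), radius, amp_c1c2 = -0.30, amp_blank = -0.20),
    roi_spec("V1",     c(12, 4, 6),  radius, amp_c1c2 =  0.20, amp_blank =  0.50)
  )
}

#' Default calcarine prior box (V1 territory for the seed search)
#' @return 3x2 matrix of voxel bounds.
#' @export
default_calcarine_prior <- function() {
  cbind(min = c(7L, 1L, 3L), max = c(18L, 7L, 9L))
}

#' Voxel indices of one scene ROI
#' @param scene a \code{scene_spec}.
#' @param label ROI label.
#' @return integer vector of linear voxel indices.
#' @export
scene_roi_voxels <- function(scene, label) {
  i <- which(vapply(scene$rois, `[[`, "", "label") == label)
  if (length(i) != 1) stop("no ROI labeled '", label, "' in scene")
  which(scene$membership == i)
}

# linear voxel indices of the prior box
prior_voxels <- function(prior, grid) {
  g <- as.matrix(expand.grid(prior[1, 1]:prior[1, 2],
                             prior[2, 1]:prior[2, 2],
                             prior[3, 1]:prior[3, 2]))
  sort(ijk_to_lin(g, grid))
}

#' Build a ground-truth ROI object from the scene
#'
#' Used in synthetic mode in place of the data-driven labeling stage.
#' @param scene a \code{scene_spec}.
#' @param label ROI label.
#' @return an object of class \code{roi}.
#' @export
scene_roi <- function(scene, label) {
  vox <- scene_roi_voxels(scene, label)
  i <- which(vapply(scene$rois, `[[`, "", "label") == label)
  new_roi(label = label, hemisphere = scene$rois[[i]]$hemisphere,
          voxels = vox, dim = scene$grid, vox_mm = scene$vox_mm,
          peak_z = NA_real_, sign = sign(scene$rois[[i]]$amp_c1c2))
}
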
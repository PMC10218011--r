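# standard-format I/O: NIfTI volumes, motion text, ground-truth sidecars

#' Write a BOLD run as a NIfTI-1 volume
#'
#' The TR is stored in the 4th pixdim; dummy count and schedule go to a YAML
#' sidecar (same path with extension \code{.yaml}) so the run round-trips.
#'
#' @param run a \code{bold_run}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_bold_nifti <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  img <- RNifti::asNifti(run$data,
                         pixdim = c(rep(run$vox_mm, 3), run$tr_s))
  RNifti::writeNifti(img, path)
  side <- list(n_dummy = run$n_dummy, tr_s = run$tr_s, vox_mm = run$vox_mm)
  if (!is.null(run$schedule)) {
    side$schedule <- run$schedule[c("tr_s", "block_s", "n_periods", "n_dummy")]
  }
  yaml::write_yaml(side, sidecar_path(path))
  invisible(path)
}

#' Read a BOLD run from NIfTI
#'
#' @param path NIfTI file written by \code{\link{write_bold_nifti}} (or any 4D
#'   NIfTI; supply \code{n_dummy}/\code{tr_s} if there is no sidecar).
#' @param n_dummy,tr_s overrides when no sidecar exists.
#' @return a \code{bold_run}.
#' @export
read_bold_nifti <- function(path, n_dummy = NULL, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  pd <- attr(RNifti::niftiHeader(img), "pixdim")
  side_file <- sidecar_path(path)
  side <- if (file.exists(side_file)) yaml::read_yaml(side_file) else list()
  if (is.null(n_dummy)) n_dummy <- side$n_dummy %||% 0L
  if (is.null(tr_s)) tr_s <- side$tr_s %||% RNifti::pixdim(img)[4]
  sched <- if (!is.null(side$schedule)) {
    do.call(make_condition_schedule, side$schedule)
  } else NULL
  bold_run(array(as.numeric(img), dim(img)), tr_s, n_dummy, sched,
           vox_mm = RNifti::pixdim(img)[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".yaml", path)
}

#' Write a motion trace as 6-column whitespace-delimited text
#' @param trace a \code{motion_trace}.
#' @param path output file.
#' @export
write_motion_trace <- function(trace, path) {
  trace <- as_motion_trace(trace)
  write.table(format(trace, digits = 10), path, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a motion trace from 6-column whitespace-delimited text
#' @param path input file (3 translations mm + 3 rotations degrees per row).
#' @return a \code{motion_trace}.
#' @export
read_motion_trace <- function(path) {
  as_motion_trace(read.table(path, header = FALSE))
}

#' Write a ground-truth record as a YAML sidecar
#' @param truth ground-truth list from a simulator.
#' @param path output file.
#' @export
write_ground_truth <- function(truth, path) {
  truth <- lapply(truth, function(x) if (is.matrix(x)) as.data.frame(x) else x)
  yaml::write_yaml(truth, path, precision = 15)
  invisible(path)
}

#' Read a ground-truth YAML sidecar
#' @param path file written by \code{\link{write_ground_truth}}.
#' @return list.
#' @export
read_ground_truth <- function(path) yaml::read_yaml(path)

#' Write a connectivity matrix as CSV with the fixed 7-label header
#' @param mat a \code{connectivity_matrix} (or 7x7 matrix).
#' @param path output file.
#' @export
write_connectivity_csv <- function(mat, path) {
  m <- unclass(mat)
  dimnames(m) <- list(ROI_ORDER, ROI_ORDER)
  write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' Read a connectivity matrix CSV
#' @param path file written by \code{\link{write_connectivity_csv}}.
#' @return a \code{connectivity_matrix}.
#' @export
read_connectivity_csv <- function(path) {
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  dimnames(m) <- list(ROI_ORDER, ROI_ORDER)
  structure(m, class = c("connectivity_matrix", "matrix"),
            n_timepoints = NA_integer_)
}
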
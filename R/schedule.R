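#' Build a block-design condition schedule
#'
#' Describes the two-condition alternating block paradigm: runs start with
#' \code{n_dummy} dummy scans (discarded while the MR signal stabilises),
#' followed by \code{n_periods} stimulation periods, each period being one C1
#' block followed by one C2 block of equal duration.  The default reproduces
#' the acquisition used throughout: TR 3 s, 21 s blocks, 6 periods and 4
#' dummies, i.e. 88 acquired and 84 retained time points with a 14-TR period.
#'
#' @param tr_s repetition time in seconds.
#' @param block_s duration of one block in seconds; must be a multiple of
#'   \code{tr_s}.
#' @param n_periods number of complete C1+C2 periods.
#' @param n_dummy number of initial dummy scans.
#' @return an object of class \code{condition_schedule} with the block length,
#'   period length and retained run length in TRs, and the fundamental
#'   frequency in cycles per retained run (= \code{n_periods}).
#' @examples
#' sched <- make_condition_schedule(3, 21, 6, 4)
#' sched$n_total    # 88
#' sched$period_len # 14
#' @export
make_condition_schedule <- function(tr_s = 3, block_s = 21, n_periods = 6,
                                    n_dummy = 4) {
  stopifnot(tr_s > 0, block_s > 0, n_periods >= 1, n_dummy >= 0)
  if (abs(block_s / tr_s - round(block_s / tr_s)) > 1e-9) {
    stop("invalid schedule: block duration (", block_s,
         " s) is not a multiple of the TR (", tr_s, " s)")
  }
  block_len <- as.integer(round(block_s / tr_s))
  period_len <- 2L * block_len
  n_retained <- n_periods * period_len
  structure(list(
    tr_s = tr_s, block_s = block_s, n_periods = as.integer(n_periods),
    n_dummy = as.integer(n_dummy), block_len = block_len,
    period_len = period_len, period_s = 2 * block_s,
    n_retained = as.integer(n_retained),
    n_total = as.integer(n_retained + n_dummy),
    fundamental = as.integer(n_periods)
  ), class = "condition_schedule")
}

#' Condition boxcar regressor
#'
#' The stimulus profile on the retained time points: 1 during C1 blocks, 0
#' during C2 blocks, so that a GLM weight on this regressor measures the
#' C1 minus C2 response directly.
#'
#' @param schedule a \code{condition_schedule}.
#' @return numeric vector of length \code{schedule$n_retained}.
#' @export
boxcar_regressor <- function(schedule) {
  stopifnot(inherits(schedule, "condition_schedule"))
  rep(rep(c(1, 0), each = schedule$block_len), schedule$n_periods)
}

#' @export
print.condition_schedule <- function(x, ...) {
  cat(sprintf(
    "block-design schedule: TR %g s, %d x (%g s C1 + %g s C2), %d dummies\n",
    x$tr_s, x$n_periods, x$block_s, x$block_s, x$n_dummy))
  cat(sprintf("  %d time points acquired, %d retained, period %d TRs\n",
              x$n_total, x$n_retained, x$period_len))
  invisible(x)
}
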
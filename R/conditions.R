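#' Bimanual tracking task conditions
#'
#' The task crosses three inter-hand frequency ratios. In `ONE_ONE` both
#' hands rotate at the same rate; in `ONE_THREE` the right hand rotates
#' three times faster than the left, in `THREE_ONE` the left three times
#' faster than the right. Left-dial rotation drives the cursor ordinate
#' (y), right-dial rotation the abscissa (x), so the target line for a
#' condition is inclined at `atan(left_factor / right_factor)` from the
#' x axis in the internal first-quadrant frame (45 degrees for `ONE_ONE`).
#'
#' @param label One of `"ONE_ONE"`, `"ONE_THREE"`, `"THREE_ONE"`.
#' @return A `btt_condition` list with fields `label`, `left_factor`,
#'   `right_factor` and `line_angle` (radians).
#' @export
#' @examples
#' btt_condition("ONE_THREE")$line_angle  # atan(1/3)
btt_condition <- function(label) {
  label <- match.arg(label, c("ONE_ONE", "ONE_THREE", "THREE_ONE"))
  factors <- switch(label,
    ONE_ONE   = c(1L, 1L),
    ONE_THREE = c(1L, 3L),
    THREE_ONE = c(3L, 1L)
  )
  structure(
    list(
      label = label,
      left_factor = factors[[1L]],
      right_factor = factors[[2L]],
      line_angle = atan2(factors[[1L]], factors[[2L]])
    ),
    class = "btt_condition"
  )
}

#' All task conditions
#' @return Named list of the three `btt_condition` objects.
#' @export
btt_conditions <- function() {
  labels <- c("ONE_ONE", "ONE_THREE", "THREE_ONE")
  stats::setNames(lapply(labels, btt_condition), labels)
}

#' Trial timeline constants
#'
#' One trial is 1 s rest, 2 s planning, 5 s execution; EEG epochs are cut
#' from -3 to 3.5 s with 0 s at execution onset. Analysis windows: planning
#' (-2, 0) s, execution (1, 3) s (the first second of execution is skipped
#' to avoid movement-initiation artefacts), rest (-3, -2) s, and the dB
#' baseline window (-2.5, -2.2) s which lies inside the rest stage.
#'
#' @return A `trial_timeline` list of window constants, in seconds.
#' @export
trial_timeline <- function() {
  tl <- list(
    rest_s = 1, plan_s = 2, exec_s = 5,
    epoch_start_s = -3, epoch_end_s = 3.5,
    plan_window = c(-2, 0),
    exec_window = c(1, 3),
    rest_window = c(-3, -2),
    baseline_window = c(-2.5, -2.2)
  )
  stopifnot(
    tl$epoch_start_s < tl$epoch_end_s,
    tl$plan_window[1] >= tl$epoch_start_s,
    tl$exec_window[2] <= tl$epoch_end_s,
    tl$exec_window[1] >= 1  # first second of execution excluded
  )
  structure(tl, class = "trial_timeline")
}

#' Trial and session durations
#'
#' @param schedule A `session_schedule` (see [make_schedule()]).
#' @return List with `trial_s`, `block_s`, `session_s`.
#' @export
session_durations <- function(schedule) {
  tl <- trial_timeline()
  trial_s <- tl$rest_s + tl$plan_s + tl$exec_s
  per_block <- nrow(schedule$trials) / schedule$n_blocks
  list(
    trial_s = trial_s,
    block_s = trial_s * per_block,
    session_s = trial_s * nrow(schedule$trials)
  )
}
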
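#' Target trajectory for one trial
#'
#' The target dot moves at constant speed along the condition's inclined
#' line during the 5 s execution stage. Distances are normalized so the
#' line has length 1: scores are scale-free and comparable across
#' conditions.
#'
#' @param condition A `btt_condition`.
#' @param timeline A `trial_timeline` (defaults to the standard one).
#' @param fs Sampling rate of the dial encoder, Hz (default 100).
#' @return A `target_trajectory` list: `positions` (n x 2 matrix), `times`
#'   (seconds from execution onset), `fs`, and `line` (origin, unit
#'   direction, length).
#' @export
target_trajectory <- function(condition, timeline = trial_timeline(), fs = 100) {
  if (timeline$exec_s <= 0) stop("execution duration must be positive", call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  n <- round(timeline$exec_s * fs)
  s <- seq_len(n) / n                      # arc length 1/n, 2/n, ..., 1
  dir <- c(cos(condition$line_angle), sin(condition$line_angle))
  structure(
    list(
      positions = cbind(x = s * dir[1], y = s * dir[2]),
      times = seq_len(n) / fs,
      fs = fs,
      line = list(origin = c(0, 0), direction = dir, length = 1),
      condition = condition$label
    ),
    class = "target_trajectory"
  )
}

#' Participant behavior profile
#'
#' Generator parameters standing in for unobserved participant behavior.
#' `motor_noise_sd` is the standard deviation of zero-mean Gaussian noise
#' added per sample to each hand's angular displacement increment
#' (normalized line units); `lag_s` is a pure tracking delay; `coupling`
#' in [0, 1] pulls the slow hand's velocity toward the fast hand's during
#' the non-iso-frequency conditions (the classic tendency of coupled limbs
#' to drift toward a common frequency).
#'
#' @param group `"YOUNGER"` or `"OLDER"`.
#' @param motor_noise_sd,lag_s,coupling Override the group defaults.
#' @return A `participant_profile` list.
#' @export
participant_profile <- function(group = c("YOUNGER", "OLDER"),
                                motor_noise_sd = NULL, lag_s = NULL,
                                coupling = NULL) {
  group <- match.arg(group)
  defaults <- default_profile_params(group)
  p <- list(
    group = group,
    motor_noise_sd = motor_noise_sd %||% defaults$motor_noise_sd,
    lag_s = lag_s %||% defaults$lag_s,
    coupling = coupling %||% defaults$coupling
  )
  if (p$motor_noise_sd < 0) stop("`motor_noise_sd` must be >= 0", call. = FALSE)
  if (p$lag_s < 0) stop("`lag_s` must be >= 0", call. = FALSE)
  if (p$coupling < 0 || p$coupling > 1) stop("`coupling` must be in [0, 1]", call. = FALSE)
  structure(p, class = "participant_profile")
}

#' Default behavior-profile parameters per age group
#'
#' Calibrated once so that simulated group/condition mean tracking errors
#' emulate the published behavioral pattern (older adults roughly twice the
#' error of younger adults; non-iso-frequency conditions worse than
#' iso-frequency).
#'
#' @param group `"YOUNGER"` or `"OLDER"`.
#' @return List of `motor_noise_sd`, `lag_s`, `coupling`.
#' @export
default_profile_params <- function(group = c("YOUNGER", "OLDER")) {
  group <- match.arg(group)
  if (group == "YOUNGER") {
    list(motor_noise_sd = 0.0024, lag_s = 0.05, coupling = 0.11)
  } else {
    list(motor_noise_sd = 0.0042, lag_s = 0.10, coupling = 0.27)
  }
}

#' Simulate one tracked trial
#'
#' Feedback-free controller: each hand's velocity equals the target's
#' per-axis velocity delayed by `lag_s`, plus independent per-sample
#' Gaussian displacement noise, plus a coupling term that pulls the slow
#' hand's velocity toward the fast hand's by fraction `coupling`. With a
#' noise-free, lag-free, uncoupled profile the cursor reproduces the
#' target exactly.
#'
#' @param condition A `btt_condition`.
#' @param profile A `participant_profile`.
#' @param timeline A `trial_timeline`.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed for the trial's noise.
#' @return A `dial_trace` list: `left_angle`, `right_angle` (cumulative
#'   normalized displacement), `times`, `fs`, `condition`.
#' @export
simulate_trial <- function(condition, profile, timeline = trial_timeline(),
                           fs = 100, seed = 1L) {
  target <- target_trajectory(condition, timeline, fs)
  n <- nrow(target$positions)
  dt <- 1 / fs
  dir <- target$line$direction
  speed <- 1 / timeline$exec_s                      # arc-length units per second
  # per-axis target velocity: x driven by right hand, y by left hand
  v_right <- dir[1] * speed
  v_left <- dir[2] * speed

  # coupling pulls the slow hand toward the fast hand's velocity
  if (condition$left_factor > condition$right_factor) {
    v_right <- v_right + profile$coupling * (v_left - v_right)
  } else if (condition$right_factor > condition$left_factor) {
    v_left <- v_left + profile$coupling * (v_right - v_left)
  }

  times <- target$times
  active <- as.numeric(times > profile$lag_s)       # delayed velocity onset

  with_seed(seed, {
    inc_right <- v_right * dt * active + stats::rnorm(n, 0, profile$motor_noise_sd)
    inc_left <- v_left * dt * active + stats::rnorm(n, 0, profile$motor_noise_sd)
    structure(
      list(
        left_angle = cumsum(inc_left),
        right_angle = cumsum(inc_right),
        times = times,
        fs = fs,
        condition = condition$label
      ),
      class = "dial_trace"
    )
  })
}

#' Map dial rotations to cursor coordinates
#'
#' Left-dial rotation moves the cursor along the ordinate, right-dial
#' rotation along the abscissa.
#'
#' @param trace A `dial_trace`.
#' @return n x 2 matrix of cursor positions (columns `x`, `y`).
#' @export
dials_to_cursor <- function(trace) {
  cbind(x = trace$right_angle, y = trace$left_angle)
}
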
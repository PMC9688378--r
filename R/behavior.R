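#' Tracking error of one trial
#'
#' The bimanual performance score: at every execution-stage sample, the
#' Euclidean distance between cursor and target dot plus the orthogonal
#' distance from the cursor to the (infinite) target line, averaged over
#' the full 5 s trajectory. Zero iff the cursor coincides with the dot at
#' every sample; lower is better.
#'
#' @param cursor n x 2 matrix of cursor positions.
#' @param target A `target_trajectory` sampled on the same time base.
#' @return A `tracking_score` list: `value`, plus the separate
#'   `euclidean` and `orthogonal` mean components.
#' @export
#' @examples
#' tgt <- target_trajectory(btt_condition("ONE_ONE"))
#' tracking_error(tgt$positions, tgt)$value  # 0
tracking_error <- function(cursor, target) {
  cursor <- as.matrix(cursor)
  if (nrow(cursor) == 0L) stop("empty cursor input", call. = FALSE)
  if (nrow(cursor) != nrow(target$positions)) {
    stop("cursor and target must be sampled on the same time base ",
         "(lengths ", nrow(cursor), " vs ", nrow(target$positions), ")",
         call. = FALSE)
  }
  d <- cursor - target$positions
  euclid <- sqrt(d[, 1]^2 + d[, 2]^2)
  # orthogonal distance to the infinite target line through origin
  dir <- target$line$direction
  rel <- cbind(cursor[, 1] - target$line$origin[1],
               cursor[, 2] - target$line$origin[2])
  orth <- abs(rel[, 1] * dir[2] - rel[, 2] * dir[1])
  structure(
    list(
      value = mean(euclid + orth),
      euclidean = mean(euclid),
      orthogonal = mean(orth)
    ),
    class = "tracking_score"
  )
}

#' Simulate and score a full behavioral session
#'
#' Runs every scheduled trial for one participant and scores it.
#'
#' @param participant Participant id (character or integer).
#' @param group `"YOUNGER"` or `"OLDER"`.
#' @param profile A `participant_profile`.
#' @param schedule A `session_schedule`.
#' @param timeline A `trial_timeline`.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed; per-trial seeds are derived from it.
#' @return data.frame with one row per trial: `participant`, `group`,
#'   `block`, `trial`, `condition`, `tracking_error`.
#' @export
simulate_session <- function(participant, group, profile, schedule,
                             timeline = trial_timeline(), fs = 100, seed = 1L) {
  conds <- btt_conditions()
  targets <- lapply(conds, target_trajectory, timeline = timeline, fs = fs)
  trials <- schedule$trials
  err <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    cond <- conds[[trials$condition[i]]]
    tr <- simulate_trial(cond, profile, timeline, fs,
                         seed = derive_seed(seed, paste0("trial", i)))
    err[i] <- tracking_error(dials_to_cursor(tr), targets[[cond$label]])$value
  }
  data.frame(
    participant = rep(as.character(participant), nrow(trials)),
    group = rep(group, nrow(trials)),
    block = trials$block,
    trial = trials$trial,
    condition = trials$condition,
    tracking_error = err,
    stringsAsFactors = FALSE
  )
}

#' Assemble the per-trial behavior table for a cohort
#'
#' @param sessions List of per-participant session data.frames (as
#'   returned by [simulate_session()]).
#' @return One data.frame with a stable column order; empty input gives an
#'   empty table with the same columns. Incomplete sessions (fewer trials
#'   than the modal count) are reported via a warning.
#' @export
behavior_table <- function(sessions) {
  cols <- c("participant", "group", "block", "trial", "condition", "tracking_error")
  if (length(sessions) == 0L) {
    out <- data.frame(participant = character(), group = character(),
                      block = integer(), trial = integer(),
                      condition = character(), tracking_error = numeric(),
                      stringsAsFactors = FALSE)
    return(out[, cols])
  }
  out <- do.call(rbind, lapply(sessions, function(s) s[, cols]))
  rownames(out) <- NULL
  counts <- table(out$participant)
  if (length(unique(counts)) > 1L) {
    modal <- as.integer(names(sort(table(counts), decreasing = TRUE))[1L])
    short <- names(counts)[counts != modal]
    warning("incomplete session(s) for participant(s): ",
            paste(short, collapse = ", "), call. = FALSE)
  }
  out
}
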
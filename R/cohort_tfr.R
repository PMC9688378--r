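#' Trial-averaged, dB-normalized TFRs for a whole cohort
#'
#' For every participant x electrode x condition, averages raw Morlet
#' power across trials, then dB-normalizes each condition's average
#' against the across-condition baseline of that participant x electrode
#' (per-condition baselining available via `baseline`).
#'
#' @param cohort_eeg An `eeg_cohort` from [synth_cohort()].
#' @param config A `morlet_config`.
#' @param baseline `"condition_average"` (default, baseline common across
#'   conditions) or `"per_condition"`.
#' @param window Baseline window, seconds.
#' @return List of dB `tfr` objects (one per participant x electrode x
#'   condition) carrying `participant`, `group`, `electrode`, `condition`.
#' @export
cohort_tfr <- function(cohort_eeg, config = morlet_config(),
                       baseline = c("condition_average", "per_condition"),
                       window = trial_timeline()$baseline_window) {
  baseline <- match.arg(baseline)
  epochs <- cohort_eeg$epochs
  channels <- epochs[[1L]]$channels
  key <- function(p, cond) paste(p, cond, sep = "|")

  # accumulate per participant|condition: sum over trials of power arrays
  acc <- list()
  counts <- list()
  for (ep in epochs) {
    k <- key(ep$participant, ep$condition)
    tf <- morlet_epoch(ep, config)
    if (is.null(acc[[k]])) {
      acc[[k]] <- tf$power
      counts[[k]] <- 1L
      grid_freqs <- tf$freqs
      grid_times <- tf$times
    } else {
      acc[[k]] <- acc[[k]] + tf$power
      counts[[k]] <- counts[[k]] + 1L
    }
  }
  for (k in names(acc)) acc[[k]] <- acc[[k]] / counts[[k]]

  part_info <- unique(data.frame(
    participant = vapply(epochs, `[[`, character(1), "participant"),
    group = vapply(epochs, `[[`, character(1), "group"),
    stringsAsFactors = FALSE
  ))
  conds <- unique(vapply(epochs, `[[`, character(1), "condition"))

  out <- list()
  cols <- which(grid_times >= window[1] & grid_times <= window[2])
  if (length(cols) == 0L) stop("baseline window not on the TFR grid", call. = FALSE)
  for (i in seq_len(nrow(part_info))) {
    p <- part_info$participant[i]
    for (j in seq_along(channels)) {
      mats <- lapply(conds, function(cond) acc[[key(p, cond)]][j, , ])
      for (ci in seq_along(conds)) {
        B_src <- if (baseline == "condition_average") mats else mats[ci]
        B <- rowMeans(Reduce(`+`, B_src)[, cols, drop = FALSE]) / length(B_src)
        if (any(B <= 0)) stop("baseline power must be strictly positive", call. = FALSE)
        out[[length(out) + 1L]] <- structure(
          list(power = 10 * log10(sweep(mats[[ci]], 1, B, "/")),
               freqs = grid_freqs, times = grid_times, scale = "DB",
               baseline_window = window,
               participant = p, group = part_info$group[i],
               electrode = channels[j], condition = conds[ci]),
          class = "tfr"
        )
      }
    }
  }
  out
}
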
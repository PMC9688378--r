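#' Sample a study cohort
#'
#' Draws per-participant behavior parameters around the group defaults.
#' A latent per-participant `skill_z` (standard normal; higher = worse
#' performer) scales motor noise and coupling multiplicatively, creating
#' between-participant variance in tracking error. The same latent is
#' reused by the EEG generator to couple planning-stage beta
#' desynchronization to behavioral skill, which is the association the
#' statistics layer must detect.
#'
#' @param n_younger,n_older Participants per age group (study sizes: 20
#'   younger, 19 older).
#' @param seed Integer seed.
#' @return data.frame with one row per participant: `participant`,
#'   `group`, `skill_z`, `motor_noise_sd`, `lag_s`, `coupling`.
#' @export
make_cohort <- function(n_younger = 20L, n_older = 19L, seed = 1L) {
  stopifnot(n_younger >= 1L, n_older >= 1L)
  groups <- c(rep("YOUNGER", n_younger), rep("OLDER", n_older))
  with_seed(seed, {
    n <- length(groups)
    skill <- stats::rnorm(n)
    lag_jit <- stats::rnorm(n, 0, 0.2)
    rows <- lapply(seq_len(n), function(i) {
      def <- default_profile_params(groups[i])
      data.frame(
        participant = sprintf("P%02d", i),
        group = groups[i],
        skill_z = skill[i],
        motor_noise_sd = def$motor_noise_sd * exp(0.35 * skill[i]),
        lag_s = def$lag_s * exp(lag_jit[i]),
        coupling = min(1, def$coupling * exp(0.30 * skill[i])),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Simulate behavior for a whole cohort
#'
#' One scheduled session per participant, scored per trial.
#'
#' @param cohort data.frame from [make_cohort()].
#' @param n_blocks,trials_per_condition Session structure (defaults: 4
#'   blocks, 13 trials per condition per block).
#' @param fs Dial sampling rate, Hz.
#' @param seed Integer seed.
#' @return Per-trial behavior table (see [behavior_table()]).
#' @export
simulate_cohort_behavior <- function(cohort, n_blocks = 4L,
                                     trials_per_condition = 13L,
                                     fs = 100, seed = 1L) {
  sessions <- lapply(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    prof <- participant_profile(row$group,
                                motor_noise_sd = row$motor_noise_sd,
                                lag_s = row$lag_s,
                                coupling = row$coupling)
    sch <- make_schedule(n_blocks, trials_per_condition,
                         seed = derive_seed(seed, paste0("sched", i)))
    simulate_session(row$participant, row$group, prof, sch, fs = fs,
                     seed = derive_seed(seed, paste0("beh", i)))
  })
  behavior_table(sessions)
}
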
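#' Electrode montage of interest
#'
#' The six electrodes analysed, with their region (first letter of the
#' 10-20 label: F -> frontal, C -> central, P -> parietal) and hemisphere
#' (odd index -> left, even -> right).
#'
#' @return data.frame with `channel`, `region`, `hemisphere`.
#' @export
electrode_meta <- function() {
  data.frame(
    channel = c("F3", "F4", "C3", "C4", "P3", "P4"),
    region = c("frontal", "frontal", "central", "central", "parietal", "parietal"),
    hemisphere = c("left", "right", "left", "right", "left", "right"),
    stringsAsFactors = FALSE
  )
}

#' Default MRBD depth table
#'
#' Injected beta power change (dB, relative to rest; negative =
#' desynchronization) per group x region x hemisphere x stage x condition.
#' Execution depths are constant across conditions (no complexity effect
#' during execution); planning depths combine group-specific region means
#' with hemisphere-by-condition modulation (left-hemisphere dominance
#' overall, with the hemisphere ipsilateral to the faster hand showing
#' deeper desynchronization). The numbers emulate the published group
#' means this generator is calibrated to.
#'
#' @return data.frame keyed by `group`, `region`, `hemisphere`,
#'   `condition`, `stage` with column `depth_db`.
#' @export
default_depth_table <- function() {
  regions <- c("frontal", "central", "parietal")
  hemis <- c("left", "right")
  conds <- c("ONE_ONE", "ONE_THREE", "THREE_ONE")
  groups <- c("YOUNGER", "OLDER")

  # planning: group x region means
  plan_region <- matrix(
    c(-0.64, -1.41, -1.04,   # YOUNGER frontal/central/parietal
      -0.73, -1.12, -1.15),  # OLDER
    nrow = 2, byrow = TRUE,
    dimnames = list(groups, regions)
  )
  # planning: hemisphere x condition means
  plan_hc <- matrix(
    c(-1.00, -1.05, -1.16,   # left: 1:1, 1:3, 3:1
      -0.91, -1.06, -0.91),  # right
    nrow = 2, byrow = TRUE,
    dimnames = list(hemis, conds)
  )
  plan_grand <- mean(plan_hc)

  # execution: group x hemisphere x region, constant across conditions
  exec_tab <- rbind(
    data.frame(group = "YOUNGER", hemisphere = "left",
               region = regions, depth_db = c(-2.35, -3.76, -2.67)),
    data.frame(group = "YOUNGER", hemisphere = "right",
               region = regions, depth_db = c(-2.25, -3.82, -2.88)),
    data.frame(group = "OLDER", hemisphere = "left",
               region = regions, depth_db = c(-2.61, -4.01, -3.91)),
    data.frame(group = "OLDER", hemisphere = "right",
               region = regions, depth_db = c(-3.23, -4.684, -3.67))
  )

  grid <- expand.grid(group = groups, region = regions, hemisphere = hemis,
                      condition = conds, stage = c("planning", "execution"),
                      stringsAsFactors = FALSE)
  grid$depth_db <- NA_real_
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    grid$depth_db[i] <- if (g$stage == "planning") {
      plan_region[g$group, g$region] + plan_hc[g$hemisphere, g$condition] - plan_grand
    } else {
      exec_tab$depth_db[exec_tab$group == g$group &
                          exec_tab$hemisphere == g$hemisphere &
                          exec_tab$region == g$region]
    }
  }
  grid
}

#' Uniform depth table (for recovery experiments)
#'
#' Every cell gets the same planning and execution depth.
#'
#' @param plan_db,exec_db Depths in dB (<= 0 for desynchronization).
#' @return data.frame in the same layout as [default_depth_table()].
#' @export
uniform_depth_table <- function(plan_db, exec_db) {
  tab <- default_depth_table()
  tab$depth_db <- ifelse(tab$stage == "planning", plan_db, exec_db)
  tab
}

#' Synthetic EEG configuration
#'
#' Each channel is 1/f background noise plus a beta-band oscillation whose
#' amplitude envelope is attenuated stage-specifically: the envelope is
#' `a_rest * 10^(D/20)` within a stage window with depth D dB (amplitude
#' is modulated, so power changes by exactly D dB), with smooth raised-
#' cosine transitions at stage boundaries. The oscillation is a sum of
#' equal-amplitude, random-phase sinusoids spanning `beta_band` (a
#' band-limited beta rhythm); setting both band edges equal gives a single
#' pure sinusoid.
#'
#' @param fs Sampling rate, Hz (default 256; the pipeline is fs-agnostic).
#' @param beta_band Band of the synthesized rhythm, Hz (default 13-30).
#' @param beta_spacing Spacing of the sinusoidal components, Hz.
#' @param a_rest Named resting beta amplitude per group (arbitrary units);
#'   older adults have elevated resting beta by default.
#' @param noise_exponent 1/f background exponent (power ~ 1/f^exponent).
#' @param noise_scale RMS of the background relative to the group's
#'   `a_rest`.
#' @param depth_table Injected depth table (see [default_depth_table()]).
#' @param subject_depth_sd SD of a per-participant, per-stage depth offset
#'   (dB) shared across electrodes (between-subject MRBD heterogeneity).
#' @param electrode_depth_sd SD of per-electrode depth jitter (dB).
#' @param assoc_depth_per_skill Named per-group slope (dB per skill SD)
#'   added to the right-central planning depth: worse performers get
#'   shallower (less negative) planning MRBD, encoding the positive
#'   association between planning MRBD (dB) and tracking error. Calibrated
#'   so the older-group Spearman correlation emulates the published
#'   moderate association (target rho 0.56).
#' @param n_per_group Participants per group in the default synthetic
#'   cohort.
#' @param trials_per_condition EEG trials per condition per participant.
#' @param ramp_s Envelope transition duration at stage boundaries, s.
#' @return A `neural_config` list.
#' @export
neural_config <- function(fs = 256,
                          beta_band = c(13, 30),
                          beta_spacing = 1,
                          a_rest = c(YOUNGER = 1.0, OLDER = 1.3),
                          noise_exponent = 1.0,
                          noise_scale = 0.25,
                          depth_table = default_depth_table(),
                          subject_depth_sd = 0.5,
                          electrode_depth_sd = 0.3,
                          assoc_depth_per_skill = c(YOUNGER = 0.15, OLDER = 0.6),
                          n_per_group = 10L,
                          trials_per_condition = 12L,
                          ramp_s = 0.1) {
  beta_center <- mean(beta_band)
  if (fs < 4 * beta_center) {
    stop("`fs` too low for the beta rhythm: need fs >= 4 x beta center (",
         4 * beta_center, " Hz)", call. = FALSE)
  }
  stopifnot(
    beta_band[1] <= beta_band[2], beta_band[1] >= 13, beta_band[2] <= 30,
    noise_scale >= 0, subject_depth_sd >= 0, electrode_depth_sd >= 0,
    all(a_rest > 0), ramp_s >= 0
  )
  if (a_rest[["OLDER"]] < a_rest[["YOUNGER"]]) {
    stop("defaults require a_rest(OLDER) >= a_rest(YOUNGER)", call. = FALSE)
  }
  structure(
    list(fs = fs, beta_band = beta_band, beta_spacing = beta_spacing,
         beta_center = beta_center, a_rest = a_rest,
         noise_exponent = noise_exponent, noise_scale = noise_scale,
         depth_table = depth_table, subject_depth_sd = subject_depth_sd,
         electrode_depth_sd = electrode_depth_sd,
         assoc_depth_per_skill = assoc_depth_per_skill,
         n_per_group = as.integer(n_per_group),
         trials_per_condition = as.integer(trials_per_condition),
         ramp_s = ramp_s),
    class = "neural_config"
  )
}

#' Epoch time axis
#' @param fs Sampling rate, Hz.
#' @param timeline A `trial_timeline`.
#' @return Numeric vector of sample times (seconds, 0 = execution onset).
#' @export
epoch_times <- function(fs, timeline = trial_timeline()) {
  seq(timeline$epoch_start_s, timeline$epoch_end_s, by = 1 / fs)
}

# Stage-depth envelope in dB as a function of time: 0 during rest,
# plan_db during (-2, 0), exec_db after 0; half-cosine ramps of ramp_s
# centered on the boundaries.
depth_envelope_db <- function(times, plan_db, exec_db, ramp_s,
                              timeline = trial_timeline()) {
  t_plan <- timeline$plan_window[1]
  ramp <- function(t0) {
    if (ramp_s > 0) {
      u <- pmin(pmax((times - (t0 - ramp_s / 2)) / ramp_s, 0), 1)
      (1 - cos(pi * u)) / 2
    } else {
      as.numeric(times >= t0)
    }
  }
  f1 <- ramp(t_plan)  # 0 -> 1 across planning onset
  f2 <- ramp(0)       # 0 -> 1 across execution onset
  plan_db * (f1 - f2) + exec_db * f2
}

# 1/f-shaped Gaussian noise, one column per channel, unit RMS per column.
one_over_f_noise <- function(n, n_channels, fs, exponent) {
  white <- matrix(stats::rnorm(n * n_channels), n, n_channels)
  if (exponent == 0) return(white)
  spec <- stats::mvfft(white)
  freqs <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  shape <- c(0, freqs[-1]^(-exponent / 2))
  shaped <- Re(stats::mvfft(spec * shape, inverse = TRUE)) / n
  sds <- apply(shaped, 2, stats::sd)
  sweep(shaped, 2, sds, "/")
}

#' Synthesize one EEG epoch
#'
#' @param config A `neural_config`.
#' @param depths List with numeric vectors `plan` and `exec`: depth (dB)
#'   per channel, named after [electrode_meta()] channels.
#' @param a_rest Resting beta amplitude for this participant's group.
#' @param seed Integer seed (randomizes component phases and noise).
#' @param timeline A `trial_timeline`.
#' @return An `eeg_epoch` list: `samples` (channels x time), `times`,
#'   `fs`, `channels`.
#' @export
synth_epoch <- function(config, depths, a_rest = 1, seed = 1L,
                        timeline = trial_timeline()) {
  channels <- electrode_meta()$channel
  stopifnot(all(channels %in% names(depths$plan)),
            all(channels %in% names(depths$exec)))
  times <- epoch_times(config$fs, timeline)
  n <- length(times)
  freqs <- seq(config$beta_band[1], config$beta_band[2],
               by = max(config$beta_spacing, 1e-9))
  if (config$beta_band[1] == config$beta_band[2]) freqs <- config$beta_band[1]
  amp_comp <- a_rest / sqrt(length(freqs))   # total band power = a_rest^2 / 2

  with_seed(seed, {
    phases <- matrix(stats::runif(length(freqs) * length(channels), 0, 2 * pi),
                     length(freqs), length(channels))
    arg <- outer(2 * pi * freqs, times)      # nfreq x ntime
    noise <- if (config$noise_scale > 0) {
      one_over_f_noise(n, length(channels), config$fs, config$noise_exponent) *
        (config$noise_scale * a_rest)
    } else {
      matrix(0, n, length(channels))
    }
    samples <- matrix(0, length(channels), n,
                      dimnames = list(channels, NULL))
    for (j in seq_along(channels)) {
      ch <- channels[j]
      carrier <- amp_comp * colSums(cos(arg + phases[, j]))
      env_db <- depth_envelope_db(times, depths$plan[[ch]], depths$exec[[ch]],
                                  config$ramp_s, timeline)
      samples[j, ] <- carrier * 10^(env_db / 20) + noise[, j]
    }
    structure(
      list(samples = samples, times = times, fs = config$fs,
           channels = channels),
      class = "eeg_epoch"
    )
  })
}

#' Synthesize an EEG cohort
#'
#' Generates epochs for every participant x condition x trial, together
#' with the injected-depth ground-truth table (the recovery oracle).
#' Per-participant depths are the configured table values plus a shared
#' per-stage subject offset, per-electrode jitter, and the skill-linked
#' modulation of right-central planning depth.
#'
#' @param cohort data.frame from [make_cohort()] (columns `participant`,
#'   `group`, `skill_z`). If `NULL`, a default cohort of
#'   `config$n_per_group` per group is drawn.
#' @param config A `neural_config`.
#' @param seed Integer seed.
#' @param timeline A `trial_timeline`.
#' @return An `eeg_cohort` list: `epochs` (list; each element has
#'   `samples`, metadata fields), `ground_truth` (data.frame of injected
#'   depths per participant x electrode x condition x stage), `cohort`,
#'   `config`.
#' @export
synth_cohort <- function(cohort = NULL, config = neural_config(), seed = 1L,
                         timeline = trial_timeline()) {
  if (is.null(cohort)) {
    cohort <- make_cohort(config$n_per_group, config$n_per_group,
                          seed = derive_seed(seed, "cohort"))
  }
  gt <- assign_depths(cohort, config, seed)
  conds <- names(btt_conditions())
  epochs <- list()
  for (i in seq_len(nrow(cohort))) {
    prow <- cohort[i, ]
    p_seed <- derive_seed(seed, paste0("subj", i))
    for (ci in seq_along(conds)) {
      cond <- conds[ci]
      sel <- gt$participant == prow$participant & gt$condition == cond
      d_plan <- stats::setNames(gt$depth_plan_db[sel], gt$electrode[sel])
      d_exec <- stats::setNames(gt$depth_exec_db[sel], gt$electrode[sel])
      for (tr in seq_len(config$trials_per_condition)) {
        ep <- synth_epoch(
          config, list(plan = d_plan, exec = d_exec),
          a_rest = config$a_rest[[prow$group]],
          seed = derive_seed(p_seed, paste0("ep", ci, "_", tr)),
          timeline = timeline
        )
        ep$participant <- prow$participant
        ep$group <- prow$group
        ep$condition <- cond
        ep$trial <- tr
        epochs[[length(epochs) + 1L]] <- ep
      }
    }
  }
  structure(
    list(epochs = epochs, ground_truth = gt,
         cohort = cohort, config = config),
    class = "eeg_cohort"
  )
}

#' Injected per-participant depth table
#'
#' The configured depth table plus per-participant stage offsets,
#' per-electrode jitter, and the skill-linked modulation of the
#' right-central planning depth. This is the ground truth that
#' [synth_cohort()] injects; exposed separately so recovery experiments
#' and calibration can reason about depths without synthesizing epochs.
#'
#' @param cohort data.frame from [make_cohort()].
#' @param config A `neural_config`.
#' @param seed Integer seed (must match the one given to
#'   [synth_cohort()] for the tables to agree).
#' @return data.frame per participant x electrode x condition with
#'   `depth_plan_db` and `depth_exec_db`.
#' @export
assign_depths <- function(cohort, config = neural_config(), seed = 1L) {
  meta <- electrode_meta()
  conds <- names(btt_conditions())
  gt <- list()
  for (i in seq_len(nrow(cohort))) {
    prow <- cohort[i, ]
    p_seed <- derive_seed(seed, paste0("subj", i))
    offs <- with_seed(p_seed, list(
      stage = stats::rnorm(2, 0, config$subject_depth_sd),
      elec = matrix(stats::rnorm(nrow(meta) * 2, 0, config$electrode_depth_sd),
                    nrow(meta), 2)
    ))
    for (cond in conds) {
      d_plan <- d_exec <- numeric(nrow(meta))
      for (e in seq_len(nrow(meta))) {
        base <- config$depth_table
        sel <- base$group == prow$group & base$region == meta$region[e] &
          base$hemisphere == meta$hemisphere[e] & base$condition == cond
        d_plan[e] <- base$depth_db[sel & base$stage == "planning"] +
          offs$stage[1] + offs$elec[e, 1]
        d_exec[e] <- base$depth_db[sel & base$stage == "execution"] +
          offs$stage[2] + offs$elec[e, 2]
        if (meta$channel[e] == "C4") {
          d_plan[e] <- d_plan[e] +
            config$assoc_depth_per_skill[[prow$group]] * prow$skill_z
        }
      }
      gt[[length(gt) + 1L]] <- data.frame(
        participant = prow$participant, group = prow$group,
        electrode = meta$channel, region = meta$region,
        hemisphere = meta$hemisphere, condition = cond,
        depth_plan_db = d_plan, depth_exec_db = d_exec,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, gt)
}
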
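#' Grand-average time-frequency matrix
#'
#' Cellwise mean of dB-normalized TFRs over all participants, electrodes
#' and conditions. Blind to group labels and every other factor of
#' interest, so the mask built from it cannot bias the factor analyses.
#'
#' @param tfrs List of dB `tfr` objects on a common grid.
#' @return A dB `tfr` with the cellwise mean.
#' @export
grand_average <- function(tfrs) {
  if (length(tfrs) < 1L) stop("need at least one TFR", call. = FALSE)
  ref <- tfrs[[1L]]
  for (t in tfrs[-1L]) {
    if (!isTRUE(all.equal(t$freqs, ref$freqs)) ||
        !isTRUE(all.equal(t$times, ref$times))) {
      stop("TFR grids do not match", call. = FALSE)
    }
  }
  out <- list(power = Reduce(`+`, lapply(tfrs, `[[`, "power")) / length(tfrs),
              freqs = ref$freqs, times = ref$times, scale = ref$scale,
              baseline_window = ref$baseline_window)
  structure(out, class = "tfr")
}

#' Beta band limits (13-30 Hz)
#' @return Numeric vector `c(13, 30)`.
#' @export
beta_band <- function() c(13, 30)

#' Grand-average significance mask for one stage
#'
#' For every candidate cell (beta-band frequency row x stage-window time
#' column), the cell's grand-average value is compared against the
#' rest-stage distribution of grand-average values at that frequency
#' (all time points in the rest window) with a two-sided t-test for a
#' single new observation: `t = (x - mean_rest) / (s * sqrt(1 + 1/n))`
#' on `n - 1` degrees of freedom. This tests whether the cell value is
#' consistent with being drawn from the rest distribution, so a
#' stationary null yields essentially no inclusions at the corrected
#' threshold. A cell enters the mask iff its p-value is below the
#' Bonferroni-corrected per-cell threshold
#' `alpha / (n_frequencies_total * n_timepoints_total)` of the full
#' decomposition grid.
#'
#' @param grand A dB `tfr` from [grand_average()].
#' @param stage `"planning"` or `"execution"`.
#' @param timeline A `trial_timeline`.
#' @param alpha Family-wise level before Bonferroni division (default 0.05).
#' @param negative_only If `TRUE`, additionally require the cell value to
#'   lie below the rest mean (desynchronization-only mask). Off by
#'   default: inclusion is purely by p-value.
#' @return A `significance_mask`: `include` (logical matrix, beta rows x
#'   stage columns), `pvals`, `threshold`, `alpha`, `stage`, `freqs`,
#'   `times`, `included_fraction` (percent of candidate cells).
#' @export
build_mask <- function(grand, stage = c("planning", "execution"),
                       timeline = trial_timeline(), alpha = 0.05,
                       negative_only = FALSE) {
  stage <- match.arg(stage)
  win <- if (stage == "planning") timeline$plan_window else timeline$exec_window
  rest <- timeline$rest_window
  bb <- beta_band()
  rows <- which(grand$freqs >= bb[1] & grand$freqs <= bb[2])
  # half-open windows [a, b): a grid point on a stage boundary belongs to
  # the later stage only, so the rest sample can never contain cells that
  # are also mask candidates
  cols <- which(grand$times >= win[1] & grand$times < win[2])
  rest_cols <- which(grand$times >= rest[1] & grand$times < rest[2])
  if (length(rest_cols) < 3L) stop("need >= 3 rest time points per frequency", call. = FALSE)
  if (length(rows) == 0L || length(cols) == 0L) {
    stop("beta rows or stage columns not on the grid", call. = FALSE)
  }

  n_cells_total <- length(grand$freqs) * length(grand$times)
  threshold <- alpha / n_cells_total

  pvals <- matrix(NA_real_, length(rows), length(cols))
  include <- matrix(FALSE, length(rows), length(cols))
  nr <- length(rest_cols)
  for (i in seq_along(rows)) {
    rest_sample <- grand$power[rows[i], rest_cols]
    m <- mean(rest_sample)
    s <- stats::sd(rest_sample)
    if (s == 0) {
      stop("degenerate t-test: zero variance in the rest-stage sample at ",
           grand$freqs[rows[i]], " Hz", call. = FALSE)
    }
    mu <- grand$power[rows[i], cols]
    tstat <- (mu - m) / (s * sqrt(1 + 1 / nr))
    p <- 2 * stats::pt(-abs(tstat), df = nr - 1)
    pvals[i, ] <- p
    inc <- p < threshold
    if (negative_only) inc <- inc & (mu < m)
    include[i, ] <- inc
  }
  structure(
    list(include = include, pvals = pvals, threshold = threshold,
         alpha = alpha, stage = stage,
         freqs = grand$freqs[rows], times = grand$times[cols],
         included_fraction = 100 * mean(include)),
    class = "significance_mask"
  )
}

#' Extract masked MRBD values
#'
#' For every participant x electrode x condition dB matrix, averages the
#' dB values over the cells of the stage's significance mask, yielding
#' one MRBD value per row key. Region and hemisphere are derived from the
#' electrode label.
#'
#' @param tfrs List of dB `tfr` objects carrying `participant`, `group`,
#'   `electrode`, `condition`.
#' @param mask A `significance_mask` (one stage), or a named list of
#'   masks (`planning`, `execution`) to extract both stages.
#' @return data.frame keyed by participant, group, electrode, region,
#'   hemisphere, condition, stage, with column `mrbd_db`.
#' @export
extract_mrbd <- function(tfrs, mask) {
  masks <- if (inherits(mask, "significance_mask")) {
    stats::setNames(list(mask), mask$stage)
  } else {
    mask
  }
  meta <- electrode_meta()
  out <- list()
  for (stage in names(masks)) {
    mk <- masks[[stage]]
    if (!any(mk$include)) {
      stop("empty significance mask for stage '", stage, "'", call. = FALSE)
    }
    for (tf in tfrs) {
      rows <- match(mk$freqs, tf$freqs)
      cols <- match(mk$times, tf$times)
      if (anyNA(rows) || anyNA(cols)) stop("mask and TFR grids do not match", call. = FALSE)
      sub <- tf$power[rows, cols, drop = FALSE]
      e <- match(tf$electrode, meta$channel)
      out[[length(out) + 1L]] <- data.frame(
        participant = tf$participant, group = tf$group,
        electrode = tf$electrode, region = meta$region[e],
        hemisphere = meta$hemisphere[e], condition = tf$condition,
        stage = stage, mrbd_db = mean(sub[mk$include]),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
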
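# Independent oracles used across the suite. These deliberately use
# plain per-sample loops / textbook definitions, not the package's
# vectorized implementations.

# scalar per-sample loop for the tracking score
loop_tracking_error <- function(cursor, target) {
  dir <- target$line$direction
  tot <- 0
  for (i in seq_len(nrow(cursor))) {
    eu <- sqrt(sum((cursor[i, ] - target$positions[i, ])^2))
    rel <- cursor[i, ] - target$line$origin
    orth <- abs(rel[[1]] * dir[[2]] - rel[[2]] * dir[[1]])
    tot <- tot + eu + orth
  }
  unname(tot / nrow(cursor))
}

# literal step-up definition of the BH rejection set
stepup_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  reject <- logical(m)
  if (k > 0L) reject[o[seq_len(k)]] <- TRUE
  reject
}

# midrank closed form for Spearman's rho
midrank_rho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# build a TFR object directly (for mask / averaging tests)
flat_tfr <- function(power, freqs, times, scale = "DB", ...) {
  structure(c(list(power = power, freqs = freqs, times = times,
                   scale = scale, baseline_window = c(-2.5, -2.2)),
              list(...)),
            class = "tfr")
}

# the standard decimated grid matching morlet_config() defaults at 256 Hz
default_grid <- function() {
  times <- epoch_times(256)
  list(freqs = seq(3, 35, by = 1), times = times[seq(1, length(times), by = 8)])
}

# ideal (noise-free) participant profile
ideal_profile <- function(group = "YOUNGER") {
  participant_profile(group, motor_noise_sd = 0, lag_s = 0, coupling = 0)
}
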
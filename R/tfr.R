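#' Morlet time-frequency configuration
#'
#' Frequency grid, per-frequency cycle counts, output time decimation and
#' edge handling for the complex Morlet decomposition. Cycles rise
#' linearly from 3 at 3 Hz to 12 at 35 Hz by default, trading temporal
#' for spectral resolution at higher frequencies while keeping at least
#' 90% of a pure tone's power mass within 3 Hz of the tone at every grid
#' frequency. All downstream
#' statistics are grid-agnostic: the Bonferroni mask threshold is derived
#' from whatever grid is configured.
#'
#' @param freqs Frequency grid, Hz (strictly increasing, > 0).
#' @param cycles Per-frequency wavelet cycle counts (>= 2); default
#'   linear from 3 to 12 over 3-35 Hz.
#' @param decim Output time-decimation factor (keep every `decim`-th
#'   sample).
#' @param edge Edge handling: `"reflect"` pads by one maximal wavelet
#'   half-length with the reflected signal; `"zero"` pads with zeros.
#' @return A `morlet_config` list.
#' @export
morlet_config <- function(freqs = seq(3, 35, by = 1), cycles = NULL,
                          decim = 8L, edge = c("reflect", "zero")) {
  edge <- match.arg(edge)
  if (any(freqs <= 0)) stop("frequencies must be positive", call. = FALSE)
  if (any(diff(freqs) <= 0)) stop("frequency grid must be strictly increasing", call. = FALSE)
  if (is.null(cycles)) cycles <- 3 + (freqs - 3) * (12 - 3) / (35 - 3)
  if (length(cycles) == 1L) cycles <- rep(cycles, length(freqs))
  if (length(cycles) != length(freqs)) {
    stop("`cycles` must match the frequency grid length", call. = FALSE)
  }
  if (any(cycles < 2)) stop("wavelet cycle counts must be >= 2", call. = FALSE)
  structure(
    list(freqs = freqs, cycles = cycles, decim = as.integer(decim), edge = edge),
    class = "morlet_config"
  )
}

# Precompute the frequency-domain Morlet filter bank for a given padded
# length. The wavelet at center f has temporal SD cycles/(2*pi*f); its
# Fourier transform is a Gaussian centered at +f (analytic wavelet). The
# filters are scaled so the wavelet has unit energy.
morlet_filter_bank <- function(config, nfft, fs) {
  bins <- (seq_len(nfft) - 1) * fs / nfft
  bank <- matrix(0, nfft, length(config$freqs))
  for (k in seq_along(config$freqs)) {
    f <- config$freqs[k]
    sigma_t <- config$cycles[k] / (2 * pi * f)
    # unit-energy scaling: w(t) = (sigma_t*sqrt(pi))^(-1/2) g(t) e^{i 2 pi f t}
    amp <- sqrt(sigma_t) * sqrt(2 * pi) / pi^(1 / 4)
    # distance to center on the circular frequency axis (analytic: +f only)
    d <- bins - f
    bank[, k] <- amp * exp(-2 * pi^2 * sigma_t^2 * d^2)
  }
  bank
}

# Padding layout: reflect by >= one maximal wavelet half-length
# (4 temporal SDs), rounded up so padded length is a power of two.
morlet_padding <- function(config, n, fs) {
  sigma_max <- max(config$cycles / (2 * pi * config$freqs))
  half_len <- ceiling(4 * sigma_max * fs)
  nfft <- stats::nextn(n + 2 * half_len, 2)
  pad_left <- ceiling((nfft - n) / 2)
  pad_right <- nfft - n - pad_left
  if (pad_left >= n) {  # short signals: cap reflection length
    stop("signal too short for the requested wavelet lengths", call. = FALSE)
  }
  list(nfft = nfft, left = pad_left, right = pad_right)
}

pad_signal <- function(x, pad, edge) {
  n <- length(x)
  if (edge == "reflect") {
    c(rev(x[2:(pad$left + 1)]), x, rev(x[(n - pad$right):(n - 1)]))
  } else {
    c(numeric(pad$left), x, numeric(pad$right))
  }
}

#' Complex Morlet time-frequency decomposition of one channel
#'
#' Convolves the signal with unit-energy complex Morlet wavelets (FFT
#' convolution against the reflect-padded signal) and returns squared
#' magnitudes on the decimated time grid.
#'
#' @param epoch An `eeg_epoch`, or a numeric vector (then `times` and
#'   `fs` must be supplied).
#' @param channel Channel label (when `epoch` is an `eeg_epoch`).
#' @param config A `morlet_config`.
#' @param times,fs Time axis and sampling rate when `epoch` is a bare
#'   vector.
#' @return A `tfr` object: `power` (freq x time, raw), `freqs`, `times`,
#'   `scale = "RAW"`, and provenance fields if present on the epoch.
#' @export
morlet_transform <- function(epoch, channel = NULL, config = morlet_config(),
                             times = NULL, fs = NULL) {
  if (inherits(epoch, "eeg_epoch")) {
    x <- epoch$samples[channel, ]
    times <- epoch$times
    fs <- epoch$fs
  } else {
    x <- as.numeric(epoch)
    if (is.null(times) || is.null(fs)) {
      stop("`times` and `fs` are required for a bare signal", call. = FALSE)
    }
  }
  if (max(config$freqs) > fs / 4) {
    stop("maximum analysis frequency exceeds fs/4 safety bound", call. = FALSE)
  }
  n <- length(x)
  pad <- morlet_padding(config, n, fs)
  bank <- morlet_filter_bank(config, pad$nfft, fs)
  X <- stats::fft(pad_signal(x, pad, config$edge))
  keep <- seq(1L, n, by = config$decim)
  power <- matrix(NA_real_, length(config$freqs), length(keep))
  for (k in seq_along(config$freqs)) {
    z <- stats::fft(X * bank[, k], inverse = TRUE) / pad$nfft
    power[k, ] <- Mod(z[pad$left + keep])^2
  }
  out <- list(power = power, freqs = config$freqs, times = times[keep],
              scale = "RAW", baseline_window = NULL)
  if (inherits(epoch, "eeg_epoch")) {
    for (f in c("participant", "group", "condition")) out[[f]] <- epoch[[f]]
  }
  if (!is.null(channel)) out$electrode <- channel
  structure(out, class = "tfr")
}

# Batched transform of a whole epoch (all channels at once via mvfft);
# numerically identical to per-channel morlet_transform.
morlet_epoch <- function(epoch, config = morlet_config()) {
  x <- epoch$samples
  fs <- epoch$fs
  if (max(config$freqs) > fs / 4) {
    stop("maximum analysis frequency exceeds fs/4 safety bound", call. = FALSE)
  }
  n <- ncol(x)
  pad <- morlet_padding(config, n, fs)
  bank <- morlet_filter_bank(config, pad$nfft, fs)
  padded <- vapply(seq_len(nrow(x)),
                   function(j) pad_signal(x[j, ], pad, config$edge),
                   numeric(pad$nfft))
  X <- stats::mvfft(padded)                    # nfft x channels
  keep <- seq(1L, n, by = config$decim)
  out <- array(NA_real_, c(nrow(x), length(config$freqs), length(keep)),
               dimnames = list(epoch$channels, NULL, NULL))
  for (k in seq_along(config$freqs)) {
    z <- stats::mvfft(X * bank[, k], inverse = TRUE) / pad$nfft
    out[, k, ] <- t(Mod(z[pad$left + keep, , drop = FALSE])^2)
  }
  list(power = out, freqs = config$freqs, times = epoch$times[keep])
}

#' Cellwise average of raw-power TFRs across trials
#'
#' @param tfrs List of `tfr` objects on identical grids.
#' @return A `tfr` with the arithmetic mean power.
#' @export
condition_average <- function(tfrs) {
  if (length(tfrs) < 1L) stop("need at least one TFR", call. = FALSE)
  ref <- tfrs[[1L]]
  for (t in tfrs[-1L]) {
    if (!isTRUE(all.equal(t$freqs, ref$freqs)) ||
        !isTRUE(all.equal(t$times, ref$times))) {
      stop("TFR grids do not match", call. = FALSE)
    }
    if (t$scale != "RAW") stop("condition_average expects raw power", call. = FALSE)
  }
  avg <- Reduce(`+`, lapply(tfrs, `[[`, "power")) / length(tfrs)
  out <- ref
  out$power <- avg
  out
}

#' dB baseline normalization
#'
#' Normalizes a raw-power TFR against the frequency-specific baseline
#' `B(f)`: the mean, over the baseline window's time points, of the
#' across-condition average power at each frequency. Output is
#' `10*log10(P(f,t)/B(f))` (power dB; amplitude conversions elsewhere use
#' `20*log10`).
#'
#' @param tfr A raw `tfr` to normalize.
#' @param baseline_source List of raw `tfr`s (one per condition, same
#'   provenance) whose cellwise average defines the baseline; pass
#'   `list(tfr)` for a per-condition baseline.
#' @param window Baseline window in seconds (default (-2.5, -2.2)).
#' @return A `tfr` with `scale = "DB"` and the recorded baseline window.
#' @export
db_normalize <- function(tfr, baseline_source,
                         window = trial_timeline()$baseline_window) {
  if (tfr$scale != "RAW") stop("input must be raw power", call. = FALSE)
  base_avg <- condition_average(baseline_source)
  cols <- which(base_avg$times >= window[1] & base_avg$times <= window[2])
  if (length(cols) == 0L) stop("baseline window not covered by the TFR time axis", call. = FALSE)
  B <- rowMeans(base_avg$power[, cols, drop = FALSE])
  if (any(B <= 0)) {
    stop("baseline power must be strictly positive at every frequency", call. = FALSE)
  }
  out <- tfr
  out$power <- 10 * log10(sweep(tfr$power, 1, B, "/"))
  out$scale <- "DB"
  out$baseline_window <- window
  out
}
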
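# Synthetic two-class motor-imagery EEG.
#
# The generator emulates the class structure of a cue-paced left/right hand
# imagery paradigm recorded at C3/Cz/C4: a common sensorimotor mu+beta
# oscillation mixed into all channels with per-channel gains, attenuated on the
# channel contralateral to the imagined hand inside the imagery window
# (event-related desynchronization), plus independent 1/f^beta noise.

#' Construct a labeled multichannel EEG trial set
#'
#' The raw-input container of the pipeline: a trials x channels x samples
#' array in microvolts, per-trial class labels (0 = left, 1 = right), the
#' sampling rate and channel names.
#'
#' @param data Numeric array, trials x channels x samples; all values finite.
#' @param labels Integer vector in \{0, 1\} (left/right), one per trial.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per channel.
#' @param trial_duration Trial length in seconds; `samples` must equal
#'   `round(fs * trial_duration)`.
#' @return An object of class `eeg_trial_set`.
#' @export
eeg_trial_set <- function(data, labels, fs,
                          channel_names = c("C3", "Cz", "C4"),
                          trial_duration = dim(data)[3] / fs) {
  if (!is.array(data) || length(dim(data)) != 3L)
    mi_stop("config", "data must be a trials x channels x samples array")
  if (any(!is.finite(data)))
    mi_stop("config", "data contains non-finite values")
  d <- dim(data)
  if (length(labels) != d[1])
    mi_stop("labels", "labels length (%d) != number of trials (%d)",
            length(labels), d[1])
  if (!all(labels %in% c(0L, 1L)))
    mi_stop("labels", "labels must be 0 (left) or 1 (right)")
  if (length(channel_names) != d[2])
    mi_stop("channels", "channel_names length (%d) != channel axis (%d)",
            length(channel_names), d[2])
  check_number(fs, "fs", lower = 1e-9)
  if (d[3] != round(fs * trial_duration))
    mi_stop("config", "samples (%d) != round(fs * trial_duration) (%d)",
            d[3], round(fs * trial_duration))
  structure(
    list(data = data, labels = as.integer(labels), fs = fs,
         channel_names = as.character(channel_names),
         trial_duration = trial_duration),
    class = "eeg_trial_set")
}

#' @export
print.eeg_trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_trial_set> %d trials x %d channels (%s) x %d samples @ %g Hz\n",
              d[1], d[2], paste(x$channel_names, collapse = ","), d[3], x$fs))
  cat(sprintf("  labels: %d left / %d right\n",
              sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}

#' Configuration for the synthetic MI-EEG generator
#'
#' @param n_trials_per_class Trials per class.
#' @param fs Sampling rate (Hz). Must exceed twice `beta_freq`.
#' @param duration Trial duration (s).
#' @param mu_freq,beta_freq Center frequencies (Hz) of the mu and beta
#'   oscillations.
#' @param erd_depth Fractional amplitude attenuation in \[0, 1\] applied to the
#'   contralateral channel inside the imagery window.
#' @param imagery_window `c(start_s, end_s)` within the trial.
#' @param noise_exponent Spectral slope beta of the 1/f^beta noise.
#' @param snr_db Signal-to-noise ratio (dB), defined full-band on the imagery
#'   window against the unattenuated per-channel oscillation power, so the
#'   noise level does not depend on the class label.
#' @param seed Integer seed; generation is bit-deterministic given the seed.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_trials_per_class = 100, fs = 128, duration = 9,
                         mu_freq = 10, beta_freq = 20, erd_depth = 0.5,
                         imagery_window = c(3, 8), noise_exponent = 1,
                         snr_db = 5, seed = 1) {
  check_number(n_trials_per_class, "n_trials_per_class", lower = 1, integer = TRUE)
  check_number(fs, "fs", lower = 1e-9)
  check_number(duration, "duration", lower = 1e-9)
  check_number(mu_freq, "mu_freq", lower = 1e-9)
  check_number(beta_freq, "beta_freq", lower = 1e-9)
  check_number(erd_depth, "erd_depth", lower = 0, upper = 1)
  if (length(imagery_window) != 2L)
    mi_stop("config", "imagery_window must be c(start_s, end_s)")
  if (!(imagery_window[1] >= 0 && imagery_window[1] < imagery_window[2] &&
        imagery_window[2] <= duration))
    mi_stop("config", "imagery_window must satisfy 0 <= start < end <= duration")
  check_number(noise_exponent, "noise_exponent", lower = 0)
  check_number(snr_db, "snr_db")
  check_number(seed, "seed", integer = TRUE)
  if (fs <= 2 * beta_freq)
    mi_stop("config", "fs must exceed 2 * beta_freq (fs = %g, beta_freq = %g)",
            fs, beta_freq)
  structure(list(n_trials_per_class = as.integer(n_trials_per_class), fs = fs,
                 duration = duration, mu_freq = mu_freq, beta_freq = beta_freq,
                 erd_depth = erd_depth, imagery_window = imagery_window,
                 noise_exponent = noise_exponent, snr_db = snr_db,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# 1/f^beta noise of length n by spectral shaping of white Gaussian noise.
pink_noise <- function(n, fs, exponent) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)           # two-sided frequency magnitude
  shape <- c(0, 1 / (f[-1]^(exponent / 2)))
  Re(stats::fft(W * shape, inverse = TRUE)) / n
}

#' Generate a synthetic two-class MI-EEG trial set
#'
#' For label = left (0) the mu/beta oscillation is attenuated by
#' `erd_depth` at C4 inside the imagery window; for label = right (1) at C3;
#' Cz is never attenuated. The noiseless class template is retained in the
#' `"template"` attribute for use as a denoising oracle.
#'
#' @param cfg A [synth_config()].
#' @return An [eeg_trial_set()] with attribute `template` (same shape as
#'   `$data`) and attribute `config`.
#' @export
generate_mi_eeg <- function(cfg) {
  if (!inherits(cfg, "synth_config")) cfg <- do.call(synth_config, cfg)
  set.seed(cfg$seed)
  n_trials <- 2L * cfg$n_trials_per_class
  n <- round(cfg$fs * cfg$duration)
  channels <- c("C3", "Cz", "C4")
  gains <- c(C3 = 1.0, Cz = 0.8, C4 = 1.0)   # common-source mixing gains
  amp_mu <- 10; amp_beta <- 5                # microvolt amplitudes
  tt <- (seq_len(n) - 1) / cfg$fs
  win <- tt >= cfg$imagery_window[1] & tt < cfg$imagery_window[2]

  labels <- rep(c(0L, 1L), length.out = n_trials)
  data <- array(0, dim = c(n_trials, 3L, n))
  template <- array(0, dim = c(n_trials, 3L, n))

  for (i in seq_len(n_trials)) {
    ph_mu <- stats::runif(1, 0, 2 * pi)
    ph_beta <- stats::runif(1, 0, 2 * pi)
    osc <- amp_mu * sin(2 * pi * cfg$mu_freq * tt + ph_mu) +
      amp_beta * sin(2 * pi * cfg$beta_freq * tt + ph_beta)
    contra <- if (labels[i] == 0L) "C4" else "C3"
    for (ch in 1:3) {
      att <- if (channels[ch] == contra) 1 - cfg$erd_depth * win else rep(1, n)
      sig <- gains[ch] * osc * att
      template[i, ch, ] <- sig
      # noise scaled against the unattenuated in-window oscillation power
      base_pow <- mean((gains[ch] * osc)[win]^2)
      noise <- pink_noise(n, cfg$fs, cfg$noise_exponent)
      npow <- mean(noise[win]^2)
      noise <- noise * sqrt(base_pow / (npow * 10^(cfg$snr_db / 10)))
      data[i, ch, ] <- sig + noise
    }
  }
  ts <- eeg_trial_set(data, labels, cfg$fs, channels, cfg$duration)
  attr(ts, "template") <- template
  attr(ts, "config") <- cfg
  ts
}

#' Per-trial, per-channel band power
#'
#' Mean power of each trial/channel in a frequency band, computed from the
#' periodogram of the (optionally windowed) signal. Used by tests and by the
#' linear band-power probe.
#'
#' @param ts An [eeg_trial_set()].
#' @param band `c(f_lo, f_hi)` in Hz.
#' @param window Optional `c(start_s, end_s)` restricting the time range.
#' @return A trials x channels numeric matrix.
#' @export
trial_band_power <- function(ts, band = c(8, 12), window = NULL) {
  d <- dim(ts$data)
  tt <- (seq_len(d[3]) - 1) / ts$fs
  keep <- if (is.null(window)) rep(TRUE, d[3]) else
    tt >= window[1] & tt < window[2]
  n <- sum(keep)
  f <- (seq_len(n) - 1) * ts$fs / n
  inband <- f >= band[1] & f <= band[2]
  out <- matrix(0, d[1], d[2], dimnames = list(NULL, ts$channel_names))
  for (i in seq_len(d[1])) for (ch in seq_len(d[2])) {
    x <- ts$data[i, ch, keep]
    px <- Mod(stats::fft(x - mean(x)))^2 / n^2
    out[i, ch] <- sum(px[inband])
  }
  out
}
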
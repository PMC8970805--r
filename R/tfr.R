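# Continuous wavelet transform (analytic Morlet) and scalogram images.
#
# The CWT is computed in the frequency domain: the analytic Morlet wavelet has
# the transfer function exp(-(s*w - w0)^2 / 2) on positive frequencies, so a
# unit-amplitude sinusoid produces a flat ridge of magnitude ~ 1/2 along the
# row whose center frequency matches it.

#' Scalogram configuration
#'
#' @param wavelet_omega0 Morlet center frequency omega0 (default 6).
#' @param f_min,f_max Frequency range in Hz (defaults 4 and 40, covering the
#'   mu and beta bands).
#' @param n_freqs Number of frequency rows (default 64).
#' @param spacing `"log"` (default) or `"linear"` frequency spacing.
#' @param out_size `c(H, W)` output image size (default `c(224, 224)`).
#' @param normalization `"per_image"` (default) or `"per_channel"` min-max
#'   scaling to \[0, 1\]. Joint (per-image) scaling preserves between-channel
#'   amplitude asymmetries — the contralateral ERD signature — that
#'   per-channel scaling cancels.
#' @return A validated list of class `tfr_config`.
#' @export
tfr_config <- function(wavelet_omega0 = 6, f_min = 4, f_max = 40,
                       n_freqs = 64, spacing = c("log", "linear"),
                       out_size = c(224, 224),
                       normalization = c("per_image", "per_channel")) {
  check_number(wavelet_omega0, "wavelet_omega0", lower = 1e-9)
  check_number(f_min, "f_min", lower = 1e-12)
  check_number(f_max, "f_max", lower = 1e-12)
  if (f_min >= f_max) mi_stop("config", "f_min must be < f_max")
  check_number(n_freqs, "n_freqs", lower = 2, integer = TRUE)
  spacing <- match.arg(spacing)
  if (length(out_size) != 2 || any(out_size < 1))
    mi_stop("config", "out_size must be c(H, W) with positive entries")
  normalization <- match.arg(normalization)
  structure(list(wavelet_omega0 = wavelet_omega0, f_min = f_min, f_max = f_max,
                 n_freqs = as.integer(n_freqs), spacing = spacing,
                 out_size = as.integer(out_size), normalization = normalization),
            class = "tfr_config")
}

#' Morlet scale/frequency conversion
#'
#' Center-frequency relation of the Morlet wavelet: a scale of `s` samples at
#' sampling rate `fs` responds maximally at `f = fs * (omega0 / (2*pi)) / s`
#' Hz; the two functions are mutually inverse.
#'
#' @param scale Scale in samples (positive).
#' @param f Frequency in Hz (positive).
#' @param omega0 Morlet center frequency.
#' @param fs Sampling rate (Hz).
#' @return Frequency in Hz, or scale in samples.
#' @export
scale_to_frequency <- function(scale, omega0 = 6, fs = 1) {
  if (any(scale <= 0) || omega0 <= 0 || fs <= 0)
    mi_stop("domain", "scale, omega0 and fs must be positive")
  fs * (omega0 / (2 * pi)) / scale
}

#' @rdname scale_to_frequency
#' @export
frequency_to_scale <- function(f, omega0 = 6, fs = 1) {
  if (any(f <= 0) || omega0 <= 0 || fs <= 0)
    mi_stop("domain", "f, omega0 and fs must be positive")
  fs * (omega0 / (2 * pi)) / f
}

cwt_freq_grid <- function(cfg) {
  if (cfg$spacing == "log")
    exp(seq(log(cfg$f_max), log(cfg$f_min), length.out = cfg$n_freqs))
  else
    seq(cfg$f_max, cfg$f_min, length.out = cfg$n_freqs)
}

#' Continuous wavelet transform magnitudes of a signal
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param cfg A [tfr_config()]; `f_max` must stay below the Nyquist frequency.
#' @return `n_freqs x length(x)` nonnegative magnitude matrix; rows ordered by
#'   the descending frequency grid (attribute `freqs`).
#' @export
cwt <- function(x, fs, cfg = tfr_config()) {
  if (!inherits(cfg, "tfr_config")) cfg <- do.call(tfr_config, cfg)
  if (any(!is.finite(x))) mi_stop("config", "signal must be finite")
  if (cfg$f_max >= fs / 2)
    mi_stop("nyquist", "f_max = %g Hz >= Nyquist (%g Hz)", cfg$f_max, fs / 2)
  n <- length(x)
  freqs <- cwt_freq_grid(cfg)
  scales <- frequency_to_scale(freqs, cfg$wavelet_omega0, fs)
  X <- stats::fft(x)
  w <- 2 * pi * c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
  out <- matrix(0, cfg$n_freqs, n)
  for (r in seq_len(cfg$n_freqs)) {
    psi <- ifelse(w > 0, exp(-(scales[r] * w - cfg$wavelet_omega0)^2 / 2), 0)
    out[r, ] <- Mod(stats::fft(X * psi, inverse = TRUE) / n)
  }
  attr(out, "freqs") <- freqs
  attr(out, "times") <- (seq_len(n) - 1) / fs
  out
}

# Bilinear interpolation matrix mapping n_in samples onto n_out positions.
bilinear_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  pos <- seq(1, n_in, length.out = n_out)
  lo <- pmin(floor(pos), n_in - 1L)
  frac <- pos - lo
  for (i in seq_len(n_out)) {
    if (n_in == 1) { W[i, 1] <- 1; next }
    W[i, lo[i]] <- 1 - frac[i]
    W[i, lo[i] + 1] <- frac[i]
  }
  W
}

resize_bilinear <- function(M, H, W) {
  bilinear_weights(nrow(M), H) %*% M %*% t(bilinear_weights(ncol(M), W))
}

#' Build a time-frequency scalogram image from one trial
#'
#' Per channel, CWT magnitudes are computed, resampled to `out_size` by
#' bilinear interpolation and min-max normalized to \[0, 1\]; the channels are
#' stacked along the third image axis (C3, Cz, C4 map to channels 1..3 in the
#' default montage). A channel with zero dynamic range is set to all-zeros
#' with a warning.
#'
#' @param trial Channels x samples numeric matrix.
#' @param fs Sampling rate (Hz).
#' @param cfg A [tfr_config()].
#' @param channel_order Names for the image channels.
#' @return An object of class `scalogram_image`: list with `pixels`
#'   (H x W x C in \[0, 1\]), `freqs` (length H, descending), `times`
#'   (length W), `channel_order`.
#' @export
make_scalogram_image <- function(trial, fs, cfg = tfr_config(),
                                 channel_order = rownames(trial) %||%
                                   c("C3", "Cz", "C4")[seq_len(nrow(trial))]) {
  if (!inherits(cfg, "tfr_config")) cfg <- do.call(tfr_config, cfg)
  trial <- as.matrix(trial)
  nch <- nrow(trial)
  if (length(channel_order) != nch)
    mi_stop("channels", "channel_order length != number of channels")
  H <- cfg$out_size[1]; W <- cfg$out_size[2]
  pixels <- array(0, dim = c(H, W, nch))
  raw <- vector("list", nch)
  for (ch in seq_len(nch)) {
    M <- cwt(trial[ch, ], fs, cfg)
    raw[[ch]] <- resize_bilinear(M, H, W)
  }
  if (cfg$normalization == "per_image") {
    lo <- min(unlist(lapply(raw, min))); hi <- max(unlist(lapply(raw, max)))
    for (ch in seq_len(nch)) {
      if (hi - lo < 1e-300) {
        mi_warn("degenerate", "zero dynamic range; image set to zeros")
        pixels[, , ch] <- 0
      } else pixels[, , ch] <- (raw[[ch]] - lo) / (hi - lo)
    }
  } else {
    for (ch in seq_len(nch)) {
      lo <- min(raw[[ch]]); hi <- max(raw[[ch]])
      if (hi - lo < 1e-300) {
        mi_warn("degenerate", "channel %s has zero dynamic range; set to zeros",
                channel_order[ch])
        pixels[, , ch] <- 0
      } else pixels[, , ch] <- (raw[[ch]] - lo) / (hi - lo)
    }
  }
  n <- ncol(trial)
  freq_grid <- cwt_freq_grid(cfg)
  structure(list(
    pixels = pixels,
    freqs = as.vector(bilinear_weights(cfg$n_freqs, H) %*% freq_grid),
    times = as.vector(bilinear_weights(n, W) %*% ((seq_len(n) - 1) / fs)),
    channel_order = channel_order),
    class = "scalogram_image")
}

#' Scalogram images for every trial of a set
#'
#' Order-preserving map of [make_scalogram_image()]; errors are rethrown with
#' the trial index attached.
#'
#' @param ts An [eeg_trial_set()].
#' @param cfg A [tfr_config()].
#' @return An object of class `scalogram_set`: list with `images`
#'   (H x W x C x N array), `labels`, `freqs`, `times`, `channel_order`.
#' @export
batch_scalograms <- function(ts, cfg = tfr_config()) {
  if (!inherits(cfg, "tfr_config")) cfg <- do.call(tfr_config, cfg)
  d <- dim(ts$data)
  H <- cfg$out_size[1]; W <- cfg$out_size[2]
  images <- array(0, dim = c(H, W, d[2], d[1]))
  first <- NULL
  for (i in seq_len(d[1])) {
    img <- tryCatch(
      make_scalogram_image(ts$data[i, , , drop = TRUE], ts$fs, cfg,
                           channel_order = ts$channel_names),
      error = function(e)
        mi_stop("trial", "trial %d: %s", i, conditionMessage(e)))
    images[, , , i] <- img$pixels
    if (is.null(first)) first <- img
  }
  structure(list(images = images, labels = ts$labels, freqs = first$freqs,
                 times = first$times, channel_order = first$channel_order),
            class = "scalogram_set")
}

#' @export
print.scalogram_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<scalogram_set> %d images, %d x %d x %d, freqs %.1f-%.1f Hz\n",
              d[4], d[1], d[2], d[3], min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Plot one channel of a scalogram image
#'
#' @param x A `scalogram_image`.
#' @param channel Image channel to display.
#' @param ... Passed to [graphics::image()].
#' @export
plot.scalogram_image <- function(x, channel = 1, ...) {
  z <- t(x$pixels[, , channel])[, rev(seq_along(x$freqs))]
  graphics::image(x = x$times, y = rev(x$freqs), z = z,
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
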
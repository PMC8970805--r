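# Discrete wavelet transform (Mallat pyramid) with symmetric boundary
# extension and redundant boundary coefficients, so that analysis followed by
# synthesis reconstructs the signal exactly (to rounding) for any length.

wavelet_filters <- function(wavelet_id) {
  # orthonormal filter banks (decomposition low/high, reconstruction low/high)
  f <- switch(wavelet_id,
    haar = list(dec_lo = c(0.7071067811865476, 0.7071067811865476)),
    db1 = list(dec_lo = c(0.7071067811865476, 0.7071067811865476)),
    db2 = list(dec_lo = c(-0.12940952255126037, 0.2241438680420134,
                          0.8365163037378079, 0.48296291314453416)),
    db4 = list(dec_lo = c(-0.010597401785069032, 0.0328830116668852,
                          0.030841381835560764, -0.18703481171909309,
                          -0.027983769416859854, 0.6308807679298589,
                          0.7148465705529157, 0.2303778133088965)),
    sym4 = list(dec_lo = c(-0.07576571478927333, -0.02963552764599851,
                           0.49761866763201545, 0.8037387518059161,
                           0.29785779560527736, -0.09921954357684722,
                           -0.012603967262037833, 0.0322231006040427)),
    db8 = list(dec_lo = c(-0.00011747678412476953, 0.0006754494064505693,
                          -0.00039174037337694705, -0.004870352993451574,
                          0.008746094047405777, 0.013981027917398282,
                          -0.044088253930794755, -0.017369301001807547,
                          0.12874742662047847, 0.0004724845739132828,
                          -0.2840155429615469, -0.015829105256349306,
                          0.5853546836542067, 0.6756307362972898,
                          0.31287159091429995, 0.05441584224310401)),
    mi_stop("config", "unknown wavelet '%s' (have haar/db1, db2, db4, db8, sym4)",
            wavelet_id))
  lo <- f$dec_lo
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)   # quadrature mirror
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi), length = L)
}

sym_extend <- function(x, k) {
  n <- length(x)
  if (k > n) {
    # repeat reflection until long enough (only relevant for very short inputs)
    y <- x
    while (length(y) < k + n + k) y <- c(rev(y), y, rev(y))
    mid <- (length(y) - n) %/% 2
    return(y)  # unreachable in practice given the n >= 2^levels precondition
  }
  c(rev(x[seq_len(k)]), x, rev(x[seq(n - k + 1, n)]))
}

dwt_step <- function(x, filt) {
  L <- filt$length
  ext <- sym_extend(x, L - 1)
  lo <- stats::convolve(ext, rev(filt$dec_lo), type = "filter")
  hi <- stats::convolve(ext, rev(filt$dec_hi), type = "filter")
  idx <- seq(2, length(lo), by = 2)
  list(approx = lo[idx], detail = hi[idx])
}

idwt_step <- function(approx, detail, filt, target_len) {
  L <- filt$length
  nc <- length(approx)
  up <- function(v) { u <- numeric(2 * nc); u[seq(1, 2 * nc, by = 2)] <- v; u }
  rec <- stats::convolve(up(approx), rev(filt$rec_lo), type = "open") +
         stats::convolve(up(detail), rev(filt$rec_hi), type = "open")
  # drop the L-2 redundant boundary samples on each side, then trim to the
  # analyzed length (the redundant pyramid can carry one extra sample)
  out <- rec[seq(L - 1, 2 * nc)]
  out[seq_len(target_len)]
}

#' Multilevel discrete wavelet analysis of a signal
#'
#' Decomposes a series into `levels` detail subbands plus a final
#' approximation, using symmetric boundary extension. The inverse,
#' [dwt_synthesize()], reproduces the input to numerical precision.
#'
#' @param x Numeric vector of length at least `2^levels`.
#' @param wavelet_id Wavelet name (`"haar"`/`"db1"`, `"db2"`, `"db4"`, `"sym4"`).
#' @param levels Decomposition depth (>= 1).
#' @return A list of class `dwt_subbands` with `approx` (deepest-level
#'   approximation), `details` (list, element 1 = finest level), and metadata
#'   needed for exact reconstruction.
#' @export
dwt_analyze <- function(x, wavelet_id = "db4", levels = 4) {
  check_number(levels, "levels", lower = 1, integer = TRUE)
  if (!is.numeric(x) || any(!is.finite(x)))
    mi_stop("config", "signal must be finite numeric")
  if (length(x) < 2^levels)
    mi_stop("depth", "signal length %d too short for %d levels", length(x), levels)
  filt <- wavelet_filters(wavelet_id)
  details <- vector("list", levels)
  lens <- integer(levels)
  a <- x
  for (k in seq_len(levels)) {
    lens[k] <- length(a)
    st <- dwt_step(a, filt)
    details[[k]] <- st$detail
    a <- st$approx
  }
  structure(list(approx = a, details = details, wavelet_id = wavelet_id,
                 levels = levels, lengths = lens),
            class = "dwt_subbands")
}

#' Multilevel discrete wavelet synthesis
#'
#' Inverse of [dwt_analyze()].
#'
#' @param subbands A `dwt_subbands` object (coefficients may be modified in
#'   place by callers, e.g. zeroed or re-projected).
#' @param wavelet_id Wavelet used for reconstruction; defaults to the one used
#'   in analysis. A mismatched wavelet does not reconstruct the signal.
#' @return Numeric vector of the original length.
#' @export
dwt_synthesize <- function(subbands, wavelet_id = subbands$wavelet_id) {
  if (!inherits(subbands, "dwt_subbands"))
    mi_stop("config", "subbands must come from dwt_analyze()")
  filt <- wavelet_filters(wavelet_id)
  a <- subbands$approx
  for (k in rev(seq_len(subbands$levels)))
    a <- idwt_step(a, subbands$details[[k]], filt, subbands$lengths[k])
  a
}

# Nominal frequency range (Hz) of each subband for a given sampling rate:
# detail level k spans (fs/2^(k+1), fs/2^k]; the approximation spans
# [0, fs/2^(levels+1)].
subband_bands <- function(fs, levels) {
  out <- lapply(seq_len(levels), function(k) c(fs / 2^(k + 1), fs / 2^k))
  names(out) <- paste0("d", seq_len(levels))
  out$approx <- c(0, fs / 2^(levels + 1))
  out
}
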
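# Multiscale PCA denoising: wavelet-decompose each channel, run PCA across
# channels within each subband, retain the leading components, re-project the
# coefficients through the retained subspace, and resynthesize.

#' Fit a PCA model on a samples x channels matrix
#'
#' Covariance uses the n - 1 denominator; loadings are the orthonormal
#' eigenvectors of the covariance, eigenvalues descending, scores are the
#' centered data projected onto the loadings, so that
#' `X_centered = T %*% t(P) + E_r` exactly when `A < m` and `E_r = 0` when
#' `A = m`.
#'
#' @param X Numeric matrix, n samples x m channels, n >= 2.
#' @param A Number of retained components (<= m), or `"auto"` to keep all.
#' @param center Subtract column means before decomposition (default TRUE).
#' @return An object of class `pca_model` with fields `loadings` (m x A),
#'   `scores` (n x A), `eigenvalues` (length m, descending), `n_components`,
#'   `column_means`, `residual` (n x m).
#' @export
fit_pca <- function(X, A = "auto", center = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 2) mi_stop("config", "PCA needs at least 2 samples")
  if (any(!is.finite(X))) mi_stop("config", "X contains non-finite values")
  m <- ncol(X)
  if (identical(A, "auto")) A <- m
  check_number(A, "A", lower = 1, integer = TRUE)
  if (A > m) mi_stop("dimension", "A = %d exceeds number of channels m = %d", A, m)
  mu <- if (center) colMeans(X) else numeric(m)
  Xc <- sweep(X, 2, mu)
  covx <- crossprod(Xc) / (nrow(X) - 1)
  eg <- eigen(covx, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  P <- eg$vectors[, seq_len(A), drop = FALSE]
  Tm <- Xc %*% P
  structure(list(loadings = P, scores = Tm, eigenvalues = lambda,
                 n_components = A, column_means = mu,
                 residual = Xc - Tm %*% t(P)),
            class = "pca_model")
}

#' Choose the number of principal components to retain
#'
#' Rules: `"kaiser"` keeps eigenvalues strictly above their mean (at least 1);
#' `"fixed:A"` keeps exactly A; `"variance:p"` keeps the smallest A whose
#' cumulative eigenvalue fraction reaches p.
#'
#' @param eigenvalues Nonnegative, descending numeric vector.
#' @param rule A string: `"kaiser"`, `"fixed:A"` or `"variance:p"`.
#' @return Integer count A in `[1, length(eigenvalues)]`.
#' @export
select_components <- function(eigenvalues, rule = "kaiser") {
  if (length(eigenvalues) == 0 || any(eigenvalues < -1e-12))
    mi_stop("config", "eigenvalues must be nonempty and nonnegative")
  if (is.unsorted(rev(eigenvalues), strictly = FALSE) &&
      any(diff(eigenvalues) > 1e-10))
    mi_stop("config", "eigenvalues must be descending")
  m <- length(eigenvalues)
  if (sum(eigenvalues) <= 0) {
    mi_warn("degenerate", "all-zero eigenvalues; retaining 1 component")
    return(1L)
  }
  if (rule == "kaiser") {
    return(max(1L, sum(eigenvalues > mean(eigenvalues))))
  }
  if (startsWith(rule, "fixed:")) {
    A <- as.integer(sub("^fixed:", "", rule))
    check_number(A, "fixed:A", lower = 1, upper = m, integer = TRUE)
    return(A)
  }
  if (startsWith(rule, "variance:")) {
    p <- as.numeric(sub("^variance:", "", rule))
    check_number(p, "variance:p", lower = 1e-12, upper = 1)
    frac <- cumsum(eigenvalues) / sum(eigenvalues)
    return(which(frac >= p - 1e-12)[1])
  }
  mi_stop("config", "unknown retention rule '%s'", rule)
}

#' MSPCA configuration
#'
#' @param wavelet_id Wavelet for the subband decomposition (default `"db4"`).
#' @param levels Decomposition depth (default 4).
#' @param retention_rule Component retention rule, see [select_components()].
#' @param center Center coefficient matrices before PCA (default TRUE).
#' @param scale Also z-score them (default FALSE; centering alone follows the
#'   usual MSPCA normalization).
#' @return A validated list of class `mspca_config`.
#' @export
mspca_config <- function(wavelet_id = "db4", levels = 4,
                         retention_rule = "kaiser", center = TRUE,
                         scale = FALSE) {
  check_number(levels, "levels", lower = 1, integer = TRUE)
  wavelet_filters(wavelet_id)  # validates the name
  structure(list(wavelet_id = wavelet_id, levels = as.integer(levels),
                 retention_rule = retention_rule, center = center,
                 scale = scale),
            class = "mspca_config")
}

# Project a coefficients-x-channels matrix onto its retained PCA subspace.
pca_reproject <- function(M, rule, center, scale) {
  sdv <- rep(1, ncol(M))
  if (scale) {
    sdv <- apply(M, 2, stats::sd)
    sdv[sdv == 0] <- 1
    M <- sweep(M, 2, sdv, "/")
  }
  pm <- fit_pca(M, A = "auto", center = center)
  A <- suppressWarnings(select_components(pm$eigenvalues, rule))
  P <- pm$loadings[, seq_len(A), drop = FALSE]
  out <- pm$scores[, seq_len(A), drop = FALSE] %*% t(P)
  out <- sweep(out, 2, pm$column_means, "+")
  sweep(out, 2, sdv, "*")
}

#' Multiscale PCA denoising of a trial set
#'
#' Per trial, each channel is wavelet-decomposed; within every subband the
#' channels' coefficients are stacked into a matrix, PCA is fitted across
#' channels, the retained-subspace projection replaces the coefficients, and
#' each channel is resynthesized. Cross-channel-correlated structure (the
#' common sensorimotor sources) survives; channel-independent noise is
#' suppressed.
#'
#' @param ts An [eeg_trial_set()] with at least 2 channels.
#' @param cfg An [mspca_config()].
#' @return A denoised [eeg_trial_set()] of identical shape (attributes such as
#'   the noiseless template are carried over).
#' @export
mspca_denoise <- function(ts, cfg = mspca_config()) {
  if (!inherits(ts, "eeg_trial_set")) mi_stop("config", "ts must be an eeg_trial_set")
  if (!inherits(cfg, "mspca_config")) cfg <- do.call(mspca_config, cfg)
  d <- dim(ts$data)
  if (d[2] < 2)
    mi_stop("unsupported", "MSPCA needs >= 2 channels (got %d)", d[2])
  out <- ts$data
  for (i in seq_len(d[1])) {
    sbs <- lapply(seq_len(d[2]), function(ch)
      dwt_analyze(ts$data[i, ch, ], cfg$wavelet_id, cfg$levels))
    # approximation band
    Ma <- sapply(sbs, function(s) s$approx)
    Ma <- pca_reproject(Ma, cfg$retention_rule, cfg$center, cfg$scale)
    for (ch in seq_len(d[2])) sbs[[ch]]$approx <- Ma[, ch]
    # detail bands
    for (k in seq_len(cfg$levels)) {
      Mk <- sapply(sbs, function(s) s$details[[k]])
      Mk <- pca_reproject(Mk, cfg$retention_rule, cfg$center, cfg$scale)
      for (ch in seq_len(d[2])) sbs[[ch]]$details[[k]] <- Mk[, ch]
    }
    for (ch in seq_len(d[2])) out[i, ch, ] <- dwt_synthesize(sbs[[ch]])
  }
  res <- eeg_trial_set(out, ts$labels, ts$fs, ts$channel_names, ts$trial_duration)
  attr(res, "template") <- attr(ts, "template")
  attr(res, "config") <- attr(ts, "config")
  res
}
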
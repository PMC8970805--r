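# PCA, wavelet pyramid, and multiscale PCA denoising.

test_that("fit_pca reproduces the closed-form 2x2 eigendecomposition", {
  # build data whose sample covariance is exactly [[2,1],[1,2]]
  base <- matrix(c(1, 1, -1, -1, 1, -1, 1, -1), 4, 2)
  base <- sweep(base, 2, colMeans(base))
  # whiten then color to the target covariance
  target <- matrix(c(2, 1, 1, 2), 2, 2)
  cw <- chol(cov(base))
  X <- base %*% solve(cw) %*% chol(target)
  expect_equal(cov(X), target, tolerance = 1e-12)

  pm <- fit_pca(X, A = 2)
  expect_equal(pm$eigenvalues, c(3, 1), tolerance = 1e-10)
  expect_equal(abs(pm$loadings[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-10)
  # orthonormal loadings and exact reconstruction with full rank
  expect_equal(crossprod(pm$loadings), diag(2), tolerance = 1e-8)
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(pm$scores %*% t(pm$loadings), Xc, tolerance = 1e-8)
  expect_equal(max(abs(pm$residual)), 0, tolerance = 1e-8)
})

test_that("duplicated channels give a zero second eigenvalue", {
  set.seed(1)
  x <- rnorm(20)
  pm <- fit_pca(cbind(x, x), A = 2)
  expect_equal(pm$eigenvalues[2], 0, tolerance = 1e-10)
  expect_miclass_error(fit_pca(cbind(x, x), A = 3), "dimension")
})

test_that("eigen-decomposition matches an independent svd oracle on random matrices", {
  set.seed(42)
  for (rep in 1:10) {
    X <- matrix(rnorm(15), 5, 3)
    pm <- fit_pca(X, A = 3)
    Xc <- sweep(X, 2, colMeans(X))
    sv <- svd(Xc)
    lam_oracle <- sv$d^2 / (nrow(X) - 1)
    expect_equal(pm$eigenvalues, lam_oracle, tolerance = 1e-8)
    for (j in 1:3)   # loadings match up to sign
      expect_equal(abs(pm$loadings[, j]), abs(sv$v[, j]), tolerance = 1e-6)
    # energy conservation: total variance equals the covariance trace
    expect_equal(sum(pm$eigenvalues), sum(diag(crossprod(Xc) / 4)),
                 tolerance = 1e-10)
  }
})

test_that("component retention rules follow their definitions", {
  expect_equal(select_components(c(3, 1), "kaiser"), 1)
  expect_equal(select_components(c(1, 1, 1, 1), "kaiser"), 1)
  expect_equal(select_components(c(4, 3, 2, 1), "variance:0.7"), 2)
  expect_equal(select_components(c(4, 3, 2, 1), "fixed:3"), 3)
  expect_warning(A <- select_components(c(0, 0, 0), "kaiser"),
                 class = "miclass_warning_degenerate")
  expect_equal(A, 1)
  expect_miclass_error(select_components(c(1, 2, 3), "kaiser"), "config")
})

test_that("the wavelet pyramid reconstructs perfectly and localizes energy", {
  set.seed(3)
  x <- rnorm(300)
  sb <- dwt_analyze(x, "db4", 4)
  expect_lt(max(abs(dwt_synthesize(sb) - x)), 1e-8)

  # constant signal: vanishing moments null the details
  sbc <- dwt_analyze(rep(2, 64), "db4", 3)
  expect_lt(max(abs(unlist(sbc$details))), 1e-10)

  # a 10 Hz sinusoid at 128 Hz concentrates in the 8-16 Hz subband (d3);
  # the longer db8 filter keeps the transition-band leakage below 20%
  fs <- 128
  t <- (0:1023) / fs
  sbs <- dwt_analyze(sin(2 * pi * 10 * t), "db8", 4)
  energies <- c(vapply(sbs$details, function(d) sum(d^2), 0),
                approx = sum(sbs$approx^2))
  expect_gt(energies[3] / sum(energies), 0.8)

  expect_miclass_error(dwt_analyze(rnorm(8), "db4", 4), "depth")
})

test_that("subband edits behave like filters; mismatched wavelets do not reconstruct", {
  fs <- 128
  t <- (0:511) / fs
  set.seed(9)
  x <- sin(2 * pi * 10 * t) + rnorm(512, sd = 0.5)
  sb <- dwt_analyze(x, "db4", 4)

  zeroed <- sb
  zeroed$approx <- zeroed$approx * 0
  for (k in seq_along(zeroed$details)) zeroed$details[[k]] <- zeroed$details[[k]] * 0
  expect_equal(max(abs(dwt_synthesize(zeroed))), 0)

  # zeroing level-1 details removes high-frequency power
  hp <- function(y) {
    p <- Mod(stats::fft(y))^2
    f <- (seq_along(y) - 1) * fs / length(y)
    sum(p[f > 32 & f < 64])
  }
  lowpassed <- sb
  lowpassed$details[[1]] <- lowpassed$details[[1]] * 0
  expect_lt(hp(dwt_synthesize(lowpassed)), 0.2 * hp(x))

  # synthesizing with a different filter bank is not the inverse
  expect_gt(max(abs(dwt_synthesize(sb, wavelet_id = "sym4") - x)), 1e-3)
})

test_that("full PC retention makes denoising an identity", {
  ts <- tiny_trials(n_per_class = 2, seed = 5)
  for (w in c("db4", "sym4")) {
    out <- mspca_denoise(ts, mspca_config(wavelet_id = w, levels = 3,
                                          retention_rule = "fixed:3"))
    expect_lt(max(abs(out$data - ts$data)), 1e-8)
  }
})

test_that("rank-1 cross-channel structure passes through unchanged", {
  set.seed(8)
  src <- sin(2 * pi * 10 * (0:255) / 64) + 0.3 * rnorm(256)
  dat <- array(0, dim = c(1, 3, 256))
  for (ch in 1:3) dat[1, ch, ] <- c(1, 0.8, 0.5)[ch] * src
  ts <- eeg_trial_set(dat, 0L, fs = 64)
  out <- mspca_denoise(ts, mspca_config(levels = 3))
  expect_lt(max(abs(out$data - ts$data)), 1e-6)
})

test_that("denoising reduces template MSE at 0 dB on nearly every trial", {
  ts <- generate_mi_eeg(synth_config(n_trials_per_class = 20, snr_db = 0,
                                     seed = 3))
  out <- mspca_denoise(ts)
  tpl <- attr(ts, "template")
  mse <- function(a) apply((a - tpl)^2, 1, mean)
  expect_gte(mean(mse(out$data) < mse(ts$data)), 0.9)
})

test_that("denoised output error is non-increasing in the input SNR", {
  err <- vapply(c(-5, 0, 5, 10), function(snr) {
    ts <- generate_mi_eeg(synth_config(n_trials_per_class = 5, snr_db = snr,
                                       seed = 17))
    out <- mspca_denoise(ts)
    mean((out$data - attr(ts, "template"))^2)
  }, 0)
  expect_true(all(diff(err) < 0))
})

test_that("single-channel input is rejected", {
  dat <- array(rnorm(64), dim = c(1, 1, 64))
  ts <- eeg_trial_set(dat, 0L, fs = 64, channel_names = "C3")
  expect_miclass_error(mspca_denoise(ts), "unsupported")
})
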
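# Focal loss, network construction, training, and feature extraction.

test_that("cross-entropy and pt follow their closed forms", {
  expect_lt(cross_entropy(1 - 1e-9, 1), 1e-6)
  expect_equal(cross_entropy(0.5, 1), log(2), tolerance = 1e-9)
  expect_equal(cross_entropy(0.5, 0), log(2), tolerance = 1e-9)
  expect_equal(cross_entropy(0.9, 0), -log(0.1), tolerance = 1e-6)
  expect_equal(pt(0.9, 1), 0.9)
  expect_equal(pt(0.9, 0), 0.1)
  expect_miclass_error(cross_entropy(1.2, 1), "domain")

  set.seed(1)
  p <- runif(200, 0.01, 0.99)
  y <- rbinom(200, 1, 0.5)
  expect_equal(cross_entropy(p, y), -log(pt(p, y)), tolerance = 1e-12)
})

test_that("focal loss matches direct evaluation and its limit identities", {
  expect_equal(focal_loss(0.9, 1, focal_params(alpha = 0.25, gamma = 2)),
               -0.25 * 0.1^2 * log(0.9), tolerance = 1e-9)
  expect_equal(focal_loss(0.9, 1, focal_params(alpha = 0.25, gamma = 2)),
               2.6342e-4, tolerance = 1e-4)
  expect_lt(focal_loss(1 - 1e-9, 1, focal_params()), 1e-8)

  set.seed(2)
  for (rep in 1:50) {
    p <- runif(1, 0.01, 0.99)
    y <- rbinom(1, 1, 0.5)
    a <- runif(1)
    g <- runif(1, 0, 5)
    at <- if (y == 1) a else 1 - a
    fl <- focal_loss(p, y, focal_params(alpha = a, gamma = g))
    expect_lte(fl, at * cross_entropy(p, y) + 1e-12)
    # gamma = 0 reduces to alpha-weighted cross-entropy
    expect_equal(focal_loss(p, y, focal_params(alpha = 0.5, gamma = 0)),
                 0.5 * cross_entropy(p, y), tolerance = 1e-12)
  }
})

test_that("network construction is deterministic with monotone capacity", {
  cfg <- net_config(feature_dim = 16, seed = 3)
  n1 <- build_feature_extractor(cfg)
  n2 <- build_feature_extractor(cfg)
  expect_identical(n1$params, n2$params)

  counts <- vapply(c("tiny", "18", "34"), function(d)
    miclass:::nn_param_count(
      build_feature_extractor(net_config(backbone_depth = d))$params), 0L)
  expect_true(all(diff(counts) > 0))
  expect_miclass_error(net_config(backbone_depth = "7"), "config")
})

test_that("a forward pass yields finite features and probabilities summing to one", {
  net <- build_feature_extractor(net_config(feature_dim = 32, seed = 1))
  img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3, 1))
  pr <- predict_proba(net, img)
  expect_equal(rowSums(pr), 1, tolerance = 1e-12)
  fm <- extract_features(net, img)
  expect_equal(ncol(fm), 32)
  expect_true(all(is.finite(fm)))
})

test_that("analytic gradients match finite differences", {
  cfg <- net_config(feature_dim = 8, seed = 2)
  net <- build_feature_extractor(cfg)
  set.seed(9)
  B <- 2; H <- 8; W <- 8
  arr <- array(runif(H * W * 3 * B), dim = c(H, W, 3, B))
  X <- miclass:::images_to_rows(arr)
  y <- c(0, 1)
  fl <- focal_params(0.25, 2)
  lossfn <- function(net) {
    fwd <- miclass:::net_forward(net, X, B, H, W)
    miclass:::focal_batch(fwd$probs, y, fl)$loss
  }
  fwd <- miclass:::net_forward(net, X, B, H, W, keep_cache = TRUE)
  fb <- miclass:::focal_batch(fwd$probs, y, fl)
  gr <- miclass:::net_backward(net, fwd, fb$dLogits)

  eps <- 1e-6
  probe <- function(path, setter, analytic) {
    np <- net; np$params <- setter(net$params, eps); lp <- lossfn(np)
    nm <- net; nm$params <- setter(net$params, -eps); lm <- lossfn(nm)
    num <- (lp - lm) / (2 * eps)
    expect_equal(analytic, num, tolerance = 1e-4)
  }
  probe("stem", function(p, d) { p$stem$W[[5]][1, 2] <- p$stem$W[[5]][1, 2] + d; p },
        gr$stem$W[[5]][1, 2])
  probe("lat", function(p, d) { p$lats$s1$W[2, 3] <- p$lats$s1$W[2, 3] + d; p },
        gr$lats$s1$W[2, 3])
  probe("block", function(p, d) {
    p$stages[[2]][[1]]$c2$W[[3]][1, 1] <- p$stages[[2]][[1]]$c2$W[[3]][1, 1] + d; p },
    gr$stages[[2]][[1]]$c2$W[[3]][1, 1])
  probe("feat", function(p, d) { p$feat$W[4, 2] <- p$feat$W[4, 2] + d; p },
        gr$feat$W[4, 2])
})

test_that("an untrained network scores in the chance band on balanced data", {
  ss <- tiny_scalograms(n_per_class = 10, erd_depth = 0.5, snr_db = 5, seed = 1)
  accs <- vapply(1:10, function(s) {
    cfg <- net_config(epochs = 0, feature_dim = 16, seed = s)
    train_network(build_feature_extractor(cfg), ss, cfg = cfg)$val_accuracy
  }, 0)
  expect_gte(mean(accs), 0.3)
  expect_lte(mean(accs), 0.7)
})

test_that("training separates strongly separable scalograms", {
  ss <- tiny_scalograms(n_per_class = 15, erd_depth = 0.9, snr_db = 20,
                        seed = 4, size = 16)
  # separability oracle: a linear probe on raw band power succeeds first
  ts <- generate_mi_eeg(synth_config(n_trials_per_class = 15, erd_depth = 0.9,
                                     snr_db = 20, seed = 4))
  bp <- trial_band_power(ts, c(8, 12), c(3, 8))
  contrast <- log(bp[, "C3"]) - log(bp[, "C4"])
  probe <- stats::glm((ts$labels == 1) ~ contrast, family = binomial)
  probe_acc <- mean((stats::fitted(probe) > 0.5) == (ts$labels == 1))
  expect_gte(probe_acc, 0.95)

  cfg <- net_config(epochs = 30, seed = 7)
  net <- train_network(build_feature_extractor(cfg), ss, cfg = cfg)
  expect_gte(net$train_accuracy, 0.95)
  # loss decreased over training
  expect_lt(tail(net$history$loss, 1), net$history$loss[1])

  net2 <- train_network(build_feature_extractor(cfg), ss, cfg = cfg)
  expect_identical(net$history, net2$history)
})

test_that("training rejects degenerate label sets", {
  ss <- tiny_scalograms(n_per_class = 3, size = 16)
  one_class <- ss
  one_class$labels <- rep(0L, length(ss$labels))
  cfg <- net_config(epochs = 1)
  expect_miclass_error(
    train_network(build_feature_extractor(cfg), one_class, cfg = cfg),
    "training")
})

test_that("feature extraction is deterministic, order-equivariant, width d", {
  ss <- tiny_scalograms(n_per_class = 3, size = 16)
  cfg <- net_config(epochs = 2, feature_dim = 24, seed = 5)
  net <- train_network(build_feature_extractor(cfg), ss, cfg = cfg)
  fm <- extract_features(net, ss)
  expect_equal(ncol(fm), 24)
  expect_equal(nrow(fm), length(ss$labels))
  perm <- rev(seq_along(ss$labels))
  ss_perm <- ss
  ss_perm$images <- ss$images[, , , perm, drop = FALSE]
  fm_perm <- extract_features(net, ss_perm)
  expect_equal(unclass(fm_perm), unclass(fm)[perm, ], ignore_attr = TRUE)
  # identical images give identical rows
  dup <- ss
  dup$images[, , , 2] <- dup$images[, , , 1]
  fm_dup <- extract_features(net, dup)
  expect_equal(fm_dup[1, ], fm_dup[2, ])
  # size mismatch is a shape error
  wrong <- array(0, dim = c(8, 8, 3, 1))
  expect_miclass_error(extract_features(net, wrong), "shape")
})
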
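# Feature-extraction network: residual backbone + feature pyramid + focal-loss
# classification head, with a designated penultimate feature layer.

#' Binary cross-entropy on a predicted probability
#'
#' `-log(p)` if `y = 1`, `-log(1 - p)` otherwise, natural logarithm;
#' probabilities are clipped to `[eps, 1 - eps]` (eps = 1e-7) before the log.
#'
#' @param p Predicted probability of class 1, in \[0, 1\]. Vectorized.
#' @param y Class label(s) in \{0, 1\}.
#' @param eps Clipping constant.
#' @return Nonnegative loss value(s).
#' @export
cross_entropy <- function(p, y, eps = 1e-7) {
  if (any(p < 0 | p > 1)) mi_stop("domain", "p must lie in [0, 1]")
  -log(pmin(pmax(pt(p, y), eps), 1 - eps))
}

#' Probability of the true class
#'
#' `p` if `y = 1`, `1 - p` otherwise, so that the cross-entropy is
#' `-log(pt(p, y))`.
#'
#' @inheritParams cross_entropy
#' @return Probability value(s).
#' @export
pt <- function(p, y) {
  if (any(p < 0 | p > 1)) mi_stop("domain", "p must lie in [0, 1]")
  ifelse(y == 1, p, 1 - p)
}

#' Focal loss parameters
#'
#' @param alpha Class-weight factor in \[0, 1\]; the weight applied to
#'   positive (y = 1) examples is `alpha`, to negatives `1 - alpha`.
#' @param gamma Focusing exponent (>= 0); `gamma = 0` reduces the focal loss
#'   to alpha-weighted cross-entropy.
#' @return A validated list of class `focal_params`.
#' @export
focal_params <- function(alpha = 0.25, gamma = 2) {
  check_number(alpha, "alpha", lower = 0, upper = 1)
  check_number(gamma, "gamma", lower = 0)
  structure(list(alpha = alpha, gamma = gamma), class = "focal_params")
}

#' Focal loss
#'
#' `FL = -alpha_t * (1 - pt)^gamma * log(pt)` with
#' `alpha_t = alpha` when `y = 1` and `1 - alpha` otherwise. Down-weights
#' well-classified examples so training concentrates on hard ones.
#'
#' @inheritParams cross_entropy
#' @param params A [focal_params()].
#' @return Nonnegative loss value(s).
#' @export
focal_loss <- function(p, y, params = focal_params(), eps = 1e-7) {
  if (!inherits(params, "focal_params")) params <- do.call(focal_params, params)
  ptv <- pmin(pmax(pt(p, y), eps), 1 - eps)
  at <- ifelse(y == 1, params$alpha, 1 - params$alpha)
  -at * (1 - ptv)^params$gamma * log(ptv)
}

#' Network configuration
#'
#' @param backbone_depth Backbone size key: `"tiny"` (8-layer, desk scale,
#'   the default), `"18"`, `"34"`, `"50"` or `"101"`. Deeper keys widen and
#'   lengthen the residual stages.
#' @param fpn_levels Number of backbone stages merged by the feature pyramid
#'   (2 or 3).
#' @param feature_dim Width d of the penultimate feature layer.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum.
#' @param val_fraction Held-out fraction carved from the training images.
#' @param in_channels Image channels expected at the input (3 for the
#'   C3/Cz/C4 montage).
#' @param seed Integer seed controlling initialization and batch order.
#' @return A validated list of class `net_config`.
#' @export
net_config <- function(backbone_depth = "tiny", fpn_levels = 3,
                       feature_dim = 256, epochs = 30, batch_size = 16,
                       learning_rate = 0.02, momentum = 0.9,
                       val_fraction = 0.2, in_channels = 3, seed = 1) {
  depths <- list(tiny = list(base = 8L, blocks = c(1L, 1L, 1L)),
                 `18` = list(base = 16L, blocks = c(2L, 2L, 2L)),
                 `34` = list(base = 16L, blocks = c(3L, 4L, 6L)),
                 `50` = list(base = 32L, blocks = c(3L, 4L, 6L)),
                 `101` = list(base = 32L, blocks = c(3L, 4L, 23L)))
  backbone_depth <- as.character(backbone_depth)
  if (!backbone_depth %in% names(depths))
    mi_stop("config", "unknown backbone_depth '%s' (have %s)", backbone_depth,
            paste(names(depths), collapse = ", "))
  check_number(fpn_levels, "fpn_levels", lower = 2, upper = 3, integer = TRUE)
  check_number(feature_dim, "feature_dim", lower = 2, integer = TRUE)
  check_number(epochs, "epochs", lower = 0, integer = TRUE)
  check_number(batch_size, "batch_size", lower = 1, integer = TRUE)
  check_number(learning_rate, "learning_rate", lower = 1e-12)
  check_number(momentum, "momentum", lower = 0, upper = 1)
  check_number(val_fraction, "val_fraction", lower = 0, upper = 0.9)
  check_number(in_channels, "in_channels", lower = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(list(backbone_depth = backbone_depth,
                 depth_spec = depths[[backbone_depth]],
                 fpn_levels = as.integer(fpn_levels),
                 feature_dim = as.integer(feature_dim),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 val_fraction = val_fraction,
                 in_channels = as.integer(in_channels),
                 seed = as.integer(seed)),
            class = "net_config")
}

#' Build an (untrained) feature-extraction network
#'
#' Three residual stages (channels C, 2C, 4C with stride-2 transitions), a
#' feature pyramid merging the top `fpn_levels` stages through 1x1 laterals
#' and nearest-neighbor top-down upsampling, a global-average-pooled feature
#' head of width `feature_dim`, and a 2-class softmax head trained with focal
#' loss. Initialization is He-normal and deterministic under the seed.
#'
#' @param cfg A [net_config()].
#' @param seed Seed for parameter initialization (default `cfg$seed`).
#' @return An object of class `feature_net`.
#' @export
build_feature_extractor <- function(cfg = net_config(), seed = cfg$seed) {
  if (!inherits(cfg, "net_config")) cfg <- do.call(net_config, cfg)
  set.seed(seed)
  C <- cfg$depth_spec$base
  blocks <- cfg$depth_spec$blocks
  chans <- c(C, 2L * C, 4L * C)
  Fch <- 4L * C
  params <- list()
  params$stem <- init_conv3(cfg$in_channels, chans[1])
  params$stages <- lapply(1:3, function(s)
    lapply(seq_len(blocks[s]), function(b)
      list(c1 = init_conv3(chans[s], chans[s]),
           c2 = init_conv3(chans[s], chans[s]))))
  params$downs <- lapply(1:2, function(s) init_conv3(chans[s], chans[s + 1]))
  fpn_from <- seq.int(4L - cfg$fpn_levels, 3L)
  params$lats <- stats::setNames(
    lapply(fpn_from, function(s) init_conv1(chans[s], Fch)),
    paste0("s", fpn_from))
  params$feat <- init_dense(Fch, cfg$feature_dim)
  params$head <- init_dense(cfg$feature_dim, 2L)
  structure(list(cfg = cfg, params = params, fpn_from = fpn_from,
                 chans = chans, Fch = Fch, seed = seed, trained = FALSE,
                 input_size = NULL),
            class = "feature_net")
}

#' @export
print.feature_net <- function(x, ...) {
  cat(sprintf("<feature_net> depth=%s, fpn_levels=%d, d=%d, %d parameters%s\n",
              x$cfg$backbone_depth, x$cfg$fpn_levels, x$cfg$feature_dim,
              nn_param_count(x$params),
              if (x$trained) sprintf(", trained (val acc %.3f)", x$val_accuracy)
              else ", untrained"))
  invisible(x)
}

# flatten an H x W x C x N image array into the engine's row layout
images_to_rows <- function(arr, ids = seq_len(dim(arr)[4])) {
  a <- arr[, , , ids, drop = FALSE]
  matrix(aperm(a, c(2, 1, 4, 3)), ncol = dim(arr)[3])
}

net_forward <- function(net, X, B, H, W, keep_cache = FALSE) {
  if (H %% 4 != 0 || W %% 4 != 0)
    mi_stop("shape", "image size must be divisible by 4 (got %dx%d)", H, W)
  p <- net$params
  res <- list(c(H, W), c(H / 2, W / 2), c(H / 4, W / 4))
  geo <- lapply(1:3, function(s) nn_geom(B, res[[s]][1], res[[s]][2], 1L))
  geod <- lapply(1:2, function(s) nn_geom(B, res[[s]][1], res[[s]][2], 2L))
  cache <- list(stage = vector("list", 3), down = vector("list", 2))

  cv <- conv3_fwd(X, p$stem, geo[[1]])
  A <- relu_fwd(cv$Y)
  if (keep_cache) cache$stem <- list(Xp = cv$Xp, A = A)

  S <- vector("list", 3)
  for (s in 1:3) {
    blocks <- p$stages[[s]]
    bc <- vector("list", length(blocks))
    for (b in seq_along(blocks)) {
      c1 <- conv3_fwd(A, blocks[[b]]$c1, geo[[s]])
      h1 <- relu_fwd(c1$Y)
      c2 <- conv3_fwd(h1, blocks[[b]]$c2, geo[[s]])
      Anew <- relu_fwd(A + c2$Y)
      if (keep_cache) bc[[b]] <- list(Xp1 = c1$Xp, h1 = h1, Xp2 = c2$Xp,
                                      Aout = Anew)
      A <- Anew
    }
    if (keep_cache) cache$stage[[s]] <- bc
    S[[s]] <- A
    if (s < 3) {
      cvd <- conv3_fwd(A, p$downs[[s]], geod[[s]])
      A <- relu_fwd(cvd$Y)
      if (keep_cache) cache$down[[s]] <- list(Xp = cvd$Xp, A = A)
    }
  }

  fpn_from <- net$fpn_from
  L <- P <- list()
  for (s in fpn_from) L[[s]] <- conv1_fwd(S[[s]], p$lats[[paste0("s", s)]])
  smax <- max(fpn_from); smin <- min(fpn_from)
  P[[smax]] <- L[[smax]]
  for (s in rev(setdiff(fpn_from, smax))) {
    up_idx <- nn_up_geom(B, res[[s + 1]][1], res[[s + 1]][2])
    P[[s]] <- L[[s]] + P[[s + 1]][up_idx, , drop = FALSE]
  }
  top <- P[[smin]]
  npix_top <- prod(res[[smin]])
  g <- gap_fwd(top, B)
  f_pre <- sweep(g %*% p$feat$W, 2, p$feat$b, "+")
  feat <- relu_fwd(f_pre)
  logits <- sweep(feat %*% p$head$W, 2, p$head$b, "+")
  probs <- softmax_rows(logits)

  out <- list(probs = probs, features = feat, logits = logits)
  if (keep_cache)
    out$cache <- c(cache, list(S = S, P = P, g = g, feat = feat, top = top,
                               res = res, geo = geo, geod = geod, B = B,
                               npix_top = npix_top, X = X))
  out
}

net_backward <- function(net, fwd, dLogits) {
  p <- net$params
  ca <- fwd$cache
  B <- ca$B
  gr <- list()

  gr$head <- list(W = crossprod(ca$feat, dLogits), b = colSums(dLogits))
  dFeat <- dLogits %*% t(p$head$W)
  dFpre <- relu_bwd(dFeat, ca$feat)
  gr$feat <- list(W = crossprod(ca$g, dFpre), b = colSums(dFpre))
  dG <- dFpre %*% t(p$feat$W)
  dTop <- gap_bwd(dG, B, ca$npix_top)

  fpn_from <- net$fpn_from
  smax <- max(fpn_from); smin <- min(fpn_from)
  dP <- vector("list", 3); dP[[smin]] <- dTop
  dL <- vector("list", 3)
  for (s in setdiff(fpn_from, smax)) {
    dL[[s]] <- dP[[s]]
    up_idx <- nn_up_geom(B, ca$res[[s + 1]][1], ca$res[[s + 1]][2])
    acc <- rowsum(dP[[s]], group = up_idx)
    dP[[s + 1]] <- if (is.null(dP[[s + 1]])) acc else dP[[s + 1]] + acc
  }
  dL[[smax]] <- dP[[smax]]

  dS <- vector("list", 3)
  gr$lats <- list()
  for (s in fpn_from) {
    lb <- conv1_bwd(dL[[s]], p$lats[[paste0("s", s)]], ca$S[[s]])
    gr$lats[[paste0("s", s)]] <- list(W = lb$dW, b = lb$db)
    dS[[s]] <- lb$dX
  }

  gr$stages <- vector("list", 3)
  gr$downs <- vector("list", 2)
  dA <- NULL
  for (s in 3:1) {
    dA <- if (is.null(dA)) dS[[s]] else
      if (is.null(dS[[s]])) dA else dA + dS[[s]]
    blocks <- p$stages[[s]]
    gblocks <- vector("list", length(blocks))
    for (b in rev(seq_along(blocks))) {
      bc <- ca$stage[[s]][[b]]
      dpre <- relu_bwd(dA, bc$Aout)
      b2 <- conv3_bwd(dpre, blocks[[b]]$c2, list(Xp = bc$Xp2), ca$geo[[s]])
      dh1 <- relu_bwd(b2$dX, bc$h1)
      b1 <- conv3_bwd(dh1, blocks[[b]]$c1, list(Xp = bc$Xp1), ca$geo[[s]])
      gblocks[[b]] <- list(c1 = list(W = b1$dW, b = b1$db),
                           c2 = list(W = b2$dW, b = b2$db))
      dA <- dpre + b1$dX
    }
    gr$stages[[s]] <- gblocks
    if (s > 1) {
      dc <- ca$down[[s - 1]]
      dpre <- relu_bwd(dA, dc$A)
      db <- conv3_bwd(dpre, p$downs[[s - 1]], list(Xp = dc$Xp),
                      ca$geod[[s - 1]])
      gr$downs[[s - 1]] <- list(W = db$dW, b = db$db)
      dA <- db$dX
    }
  }
  dpre <- relu_bwd(dA, ca$stem$A)
  sb <- conv3_bwd(dpre, p$stem, list(Xp = ca$stem$Xp),
                  ca$geo[[1]])
  gr$stem <- list(W = sb$dW, b = sb$db)
  gr
}

# focal-loss value and logit gradient for a batch
focal_batch <- function(probs, y, params, eps = 1e-7) {
  n <- nrow(probs)
  tcl <- y + 1L                       # true-class column (left=1, right=2)
  ptv <- pmin(pmax(probs[cbind(seq_len(n), tcl)], eps), 1 - eps)
  at <- ifelse(y == 1, params$alpha, 1 - params$alpha)
  g <- params$gamma
  loss <- mean(-at * (1 - ptv)^g * log(ptv))
  dpt <- at * (g * (1 - ptv)^pmax(g - 1, 0) * log(ptv) - (1 - ptv)^g / ptv)
  # d pt / d z_k = pt * (1[k == true] - s_k)
  ind <- matrix(0, n, 2); ind[cbind(seq_len(n), tcl)] <- 1
  dLogits <- (dpt * ptv) * (ind - probs) / n
  list(loss = loss, dLogits = dLogits)
}

sgd_update <- function(params, grads, vel, lr, mom) {
  step <- function(p, g, v) {
    if (is.list(p) && !is.null(p$W)) {
      if (is.null(v)) v <- list(W = if (is.list(p$W)) lapply(p$W, function(w) w * 0)
                                else p$W * 0,
                                b = p$b * 0)
      if (is.list(p$W)) {
        for (k in seq_along(p$W)) {
          v$W[[k]] <- mom * v$W[[k]] - lr * g$W[[k]]
          p$W[[k]] <- p$W[[k]] + v$W[[k]]
        }
      } else {
        v$W <- mom * v$W - lr * g$W
        p$W <- p$W + v$W
      }
      v$b <- mom * v$b - lr * g$b
      p$b <- p$b + v$b
      return(list(p = p, v = v))
    }
    out_p <- p; out_v <- if (is.null(v)) vector("list", length(p)) else v
    for (i in seq_along(p)) {
      gi <- if (!is.null(names(p))) g[[names(p)[i]]] else g[[i]]
      r <- step(p[[i]], gi, out_v[[i]])
      out_p[[i]] <- r$p; out_v[[i]] <- r$v
    }
    names(out_v) <- names(p)
    list(p = out_p, v = out_v)
  }
  step(params, grads, vel)
}

#' Train the feature network with focal loss
#'
#' Plain momentum SGD on the mean focal loss; a stratified validation split is
#' carved from the provided images. Deterministic given the seed (fixed
#' initialization and batch order).
#'
#' @param net A [build_feature_extractor()] network.
#' @param images `scalogram_set`, or H x W x C x N array.
#' @param labels Labels in \{0, 1\}; taken from the scalogram set if omitted.
#' @param cfg Training configuration; defaults to the network's own.
#' @param hyper Optional named list overriding `learning_rate`, `epochs`,
#'   `batch_size` and the focal `alpha` / `gamma`.
#' @return The network with `trained = TRUE`, `val_accuracy`,
#'   `train_accuracy` and `history` (per-epoch mean loss) attached.
#' @export
train_network <- function(net, images, labels = NULL, cfg = net$cfg,
                          hyper = list()) {
  if (inherits(images, "scalogram_set")) {
    labels <- labels %||% images$labels
    images <- images$images
  }
  if (length(dim(images)) != 4)
    mi_stop("shape", "images must be an H x W x C x N array")
  if (is.null(labels)) mi_stop("training", "labels are required")
  n <- dim(images)[4]
  if (length(labels) != n) mi_stop("training", "labels length != image count")
  if (length(unique(labels)) < 2)
    mi_stop("training", "training needs examples of both classes")
  if (min(table(labels)) < 2)
    mi_stop("training", "need >= 2 images per class")

  lr <- hyper$learning_rate %||% cfg$learning_rate
  epochs <- as.integer(hyper$epochs %||% cfg$epochs)
  batch_size <- as.integer(hyper$batch_size %||% cfg$batch_size)
  fl <- focal_params(alpha = hyper$alpha %||% 0.25,
                     gamma = hyper$gamma %||% 2)

  H <- dim(images)[1]; W <- dim(images)[2]
  if (dim(images)[3] != cfg$in_channels)
    mi_stop("shape", "expected %d image channels, got %d", cfg$in_channels,
            dim(images)[3])
  set.seed(derive_seed(cfg$seed, "split"))
  val_idx <- integer(0)
  if (cfg$val_fraction > 0) {
    for (cl in sort(unique(labels))) {
      ids <- which(labels == cl)
      k <- max(1L, round(length(ids) * cfg$val_fraction))
      val_idx <- c(val_idx, sample(ids, k))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(val_idx) == 0) val_idx <- tr_idx  # degenerate: validate on train

  set.seed(derive_seed(cfg$seed, "train"))
  vel <- NULL
  history <- numeric(epochs)
  HW <- H * W
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, length(ord), by = batch_size)) {
      ids <- ord[seq(start, min(start + batch_size - 1, length(ord)))]
      B <- length(ids)
      X <- images_to_rows(images, ids)
      fwd <- net_forward(net, X, B, H, W, keep_cache = TRUE)
      fb <- focal_batch(fwd$probs, labels[ids], fl)
      gr <- net_backward(net, fwd, fb$dLogits)
      up <- sgd_update(net$params, gr, vel, lr, cfg$momentum)
      net$params <- up$p; vel <- up$v
      ep_loss <- ep_loss + fb$loss; nb <- nb + 1
    }
    history[ep] <- ep_loss / nb
  }

  pred <- function(ids) {
    out <- integer(length(ids))
    for (start in seq(1, length(ids), by = 64)) {
      bl <- ids[seq(start, min(start + 63, length(ids)))]
      pr <- net_forward(net, images_to_rows(images, bl), length(bl), H, W)$probs
      out[seq(start, length.out = length(bl))] <- max.col(pr) - 1L
    }
    out
  }
  net$trained <- TRUE
  net$input_size <- c(H, W)
  net$val_accuracy <- mean(pred(val_idx) == labels[val_idx])
  net$train_accuracy <- mean(pred(tr_idx) == labels[tr_idx])
  net$history <- data.frame(epoch = seq_len(epochs), loss = history)
  net$focal <- fl
  net
}

#' Forward images through the network
#'
#' @param net A `feature_net`.
#' @param images `scalogram_set` or H x W x C x N array.
#' @return N x 2 matrix of class probabilities (columns left, right).
#' @export
predict_proba <- function(net, images) {
  if (inherits(images, "scalogram_set")) images <- images$images
  H <- dim(images)[1]; W <- dim(images)[2]; n <- dim(images)[4]
  check_input_size(net, images)
  out <- matrix(0, n, 2, dimnames = list(NULL, c("left", "right")))
  for (start in seq(1, n, by = 64)) {
    ids <- seq(start, min(start + 63, n))
    out[ids, ] <- net_forward(net, images_to_rows(images, ids),
                              length(ids), H, W)$probs
  }
  out
}

check_input_size <- function(net, images) {
  if (dim(images)[3] != net$cfg$in_channels)
    mi_stop("shape", "expected %d image channels, got %d",
            net$cfg$in_channels, dim(images)[3])
  if (!is.null(net$input_size) &&
      !all(dim(images)[1:2] == net$input_size))
    mi_stop("shape", "network was trained on %dx%d images, got %dx%d",
            net$input_size[1], net$input_size[2], dim(images)[1],
            dim(images)[2])
  invisible(TRUE)
}

#' Extract penultimate-layer feature vectors
#'
#' Row i is the `feature_dim`-wide activation of image i at the designated
#' feature layer (global-average-pooled top pyramid merge through the feature
#' dense layer). Deterministic.
#'
#' @inheritParams predict_proba
#' @param labels Optional labels carried along as an attribute.
#' @return A `feature_matrix`: N x d numeric matrix with attribute `labels`.
#' @export
extract_features <- function(net, images, labels = NULL) {
  if (inherits(images, "scalogram_set")) {
    labels <- labels %||% images$labels
    images <- images$images
  }
  H <- dim(images)[1]; W <- dim(images)[2]; n <- dim(images)[4]
  check_input_size(net, images)
  Fm <- matrix(0, n, net$cfg$feature_dim)
  for (start in seq(1, n, by = 64)) {
    ids <- seq(start, min(start + 63, n))
    Fm[ids, ] <- net_forward(net, images_to_rows(images, ids),
                             length(ids), H, W)$features
  }
  structure(Fm, labels = labels, class = c("feature_matrix", "matrix", "array"))
}
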
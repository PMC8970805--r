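# Internal mini convolutional-network engine.
#
# Feature maps live as (B*H*W) x C matrices (image index slowest, then rows,
# then columns), so 3x3 convolutions become nine indexed matrix products
# against zero-padded inputs — all heavy lifting goes through BLAS. Backward
# passes are written explicitly per operation; there is no general autograd.

nn_geom_cache <- new.env(parent = emptyenv())

nn_geom <- function(B, H, W, stride) {
  key <- paste(B, H, W, stride, sep = "x")
  if (!is.null(nn_geom_cache[[key]])) return(nn_geom_cache[[key]])
  Hp <- H + 2L; Wp <- W + 2L
  Ho <- (H - 1L) %/% stride + 1L
  Wo <- (W - 1L) %/% stride + 1L
  base <- rep((0:(B - 1L)) * Hp * Wp, each = Ho * Wo)
  ii <- rep(rep((seq_len(Ho) - 1L) * stride + 2L, each = Wo), times = B)
  jj <- rep(rep((seq_len(Wo) - 1L) * stride + 2L, times = Ho), times = B)
  idx <- vector("list", 9L)
  k <- 0L
  for (di in -1:1) for (dj in -1:1) {
    k <- k + 1L
    idx[[k]] <- base + (ii + di - 1L) * Wp + (jj + dj)
  }
  base2 <- rep((0:(B - 1L)) * Hp * Wp, each = H * W)
  i2 <- rep(rep(2:(H + 1L), each = W), times = B)
  j2 <- rep(rep(2:(W + 1L), times = H), times = B)
  g <- list(B = B, H = H, W = W, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo,
            idx = idx, int_idx = base2 + (i2 - 1L) * Wp + j2)
  nn_geom_cache[[key]] <- g
  g
}

nn_up_geom <- function(B, Ho, Wo) {
  key <- paste("up", B, Ho, Wo, sep = "x")
  if (!is.null(nn_geom_cache[[key]])) return(nn_geom_cache[[key]])
  H <- 2L * Ho; W <- 2L * Wo
  base <- rep((0:(B - 1L)) * Ho * Wo, each = H * W)
  hh <- rep(rep((seq_len(H) + 1L) %/% 2L, each = W), times = B)
  ww <- rep(rep((seq_len(W) + 1L) %/% 2L, times = H), times = B)
  g <- base + (hh - 1L) * Wo + ww
  nn_geom_cache[[key]] <- g
  g
}

conv3_fwd <- function(X, p, geo) {
  Cin <- ncol(X)
  Xp <- matrix(0, geo$B * geo$Hp * geo$Wp, Cin)
  Xp[geo$int_idx, ] <- X
  Y <- matrix(p$b, geo$B * geo$Ho * geo$Wo, length(p$b), byrow = TRUE)
  for (k in 1:9) Y <- Y + Xp[geo$idx[[k]], , drop = FALSE] %*% p$W[[k]]
  list(Y = Y, Xp = Xp)
}

conv3_bwd <- function(dY, p, cache, geo) {
  Cin <- nrow(p$W[[1]])
  dXp <- matrix(0, geo$B * geo$Hp * geo$Wp, Cin)
  dW <- vector("list", 9L)
  for (k in 1:9) {
    Xk <- cache$Xp[geo$idx[[k]], , drop = FALSE]
    dW[[k]] <- crossprod(Xk, dY)
    dXp[geo$idx[[k]], ] <- dXp[geo$idx[[k]], , drop = FALSE] +
      dY %*% t(p$W[[k]])
  }
  list(dX = dXp[geo$int_idx, , drop = FALSE], dW = dW, db = colSums(dY))
}

conv1_fwd <- function(X, p) sweep(X %*% p$W, 2, p$b, "+")
conv1_bwd <- function(dY, p, X)
  list(dX = dY %*% t(p$W), dW = crossprod(X, dY), db = colSums(dY))

relu_fwd <- function(X) pmax(X, 0)
relu_bwd <- function(dY, Y) dY * (Y > 0)

gap_fwd <- function(X, B) {
  npix <- nrow(X) / B
  rowsum(X, group = rep(seq_len(B), each = npix)) / npix
}
gap_bwd <- function(dG, B, npix)
  dG[rep(seq_len(B), each = npix), , drop = FALSE] / npix

init_conv3 <- function(Cin, Cout) {
  sdv <- sqrt(2 / (9 * Cin))
  list(W = lapply(1:9, function(k) matrix(stats::rnorm(Cin * Cout, 0, sdv), Cin, Cout)),
       b = numeric(Cout))
}
init_conv1 <- function(Cin, Cout)
  list(W = matrix(stats::rnorm(Cin * Cout, 0, sqrt(2 / Cin)), Cin, Cout),
       b = numeric(Cout))
init_dense <- function(Cin, Cout)
  list(W = matrix(stats::rnorm(Cin * Cout, 0, sqrt(2 / Cin)), Cin, Cout),
       b = numeric(Cout))

# flatten/apply parameter updates generically over the nested parameter list
nn_map_params <- function(p, f) {
  if (is.list(p) && !is.null(p$W)) return(f(p))
  lapply(p, nn_map_params, f = f)
}

nn_param_count <- function(params) {
  n <- 0L
  walk <- function(p) {
    if (is.list(p) && !is.null(p$W)) {
      w <- if (is.list(p$W)) sum(vapply(p$W, length, 0L)) else length(p$W)
      n <<- n + w + length(p$b)
    } else if (is.list(p)) lapply(p, walk)
  }
  walk(params)
  n
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}
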
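## Convolutional building blocks for the fusion network: channel-preserving
## 3x3(x3) convolutions implemented as im2col matrix products, group
## normalization, ReLU, and residual stacks. Feature maps are stored as
## `channels x positions` matrices with positions in the package's fixed
## raster order, so no array-reshape conventions can drift.

# Neighbor index map for a 3D grid (t x h x w, raster order t-major, w
# fastest) with a 3x3x3 kernel and zero padding 1. Returns a 27 x P integer
# matrix; 0 marks an out-of-bounds (zero-padded) tap.
conv_index_3d <- function(t_bar, h_bar, w_bar) {
  key <- paste("c3", t_bar, h_bar, w_bar)
  cached <- .cache_get(key)
  if (!is.null(cached)) return(cached)
  P <- t_bar * h_bar * w_bar
  i0 <- 0:(P - 1)
  w <- i0 %% w_bar; h <- (i0 %/% w_bar) %% h_bar; t <- i0 %/% (w_bar * h_bar)
  off <- expand.grid(dw = -1:1, dh = -1:1, dt = -1:1)   # dw fastest
  nb <- matrix(0L, nrow(off), P)
  for (k in seq_len(nrow(off))) {
    tt <- t + off$dt[k]; hh <- h + off$dh[k]; ww <- w + off$dw[k]
    ok <- tt >= 0 & tt < t_bar & hh >= 0 & hh < h_bar & ww >= 0 & ww < w_bar
    nb[k, ok] <- as.integer(((tt * h_bar + hh) * w_bar + ww)[ok] + 1L)
  }
  .cache_set(key, nb)
  nb
}

# Same for a 2D grid (h x w, w fastest) with 3x3 kernel, padding 1.
conv_index_2d <- function(h_bar, w_bar) {
  key <- paste("c2", h_bar, w_bar)
  cached <- .cache_get(key)
  if (!is.null(cached)) return(cached)
  P <- h_bar * w_bar
  i0 <- 0:(P - 1)
  w <- i0 %% w_bar; h <- i0 %/% w_bar
  off <- expand.grid(dw = -1:1, dh = -1:1)
  nb <- matrix(0L, nrow(off), P)
  for (k in seq_len(nrow(off))) {
    hh <- h + off$dh[k]; ww <- w + off$dw[k]
    ok <- hh >= 0 & hh < h_bar & ww >= 0 & ww < w_bar
    nb[k, ok] <- as.integer((hh * w_bar + ww)[ok] + 1L)
  }
  .cache_set(key, nb)
  nb
}

init_conv <- function(c_in, c_out, k_taps, sd = 0.02) {
  list(W = matrix(stats::rnorm(c_out * c_in * k_taps, sd = sd),
                  c_out, c_in * k_taps),
       b = numeric(c_out))
}

# im2col: X is C x P; returns (C * K) x P with zero-padded taps.
conv_cols <- function(X, nb) {
  C <- nrow(X); K <- nrow(nb); P <- ncol(nb)
  cols <- matrix(0, C * K, P)
  for (k in seq_len(K)) {
    ok <- nb[k, ] > 0L
    if (any(ok)) cols[(k - 1L) * C + seq_len(C), ok] <- X[, nb[k, ok], drop = FALSE]
  }
  cols
}

conv_fwd <- function(X, p, nb) {
  cols <- conv_cols(X, nb)
  out <- p$W %*% cols + p$b
  list(out = out, cache = list(cols = cols, nb = nb, C = nrow(X)))
}

conv_bwd <- function(dY, p, cache) {
  nb <- cache$nb; C <- cache$C
  dcols <- t(p$W) %*% dY
  dX <- matrix(0, C, ncol(nb))
  for (k in seq_len(nrow(nb))) {
    ok <- nb[k, ] > 0L
    if (any(ok)) {
      # within one kernel offset every output position maps to a distinct
      # source position, so plain indexed accumulation is exact
      tgt <- nb[k, ok]
      dX[, tgt] <- dX[, tgt] + dcols[(k - 1L) * C + seq_len(C), ok, drop = FALSE]
    }
  }
  list(dX = dX,
       grads = list(W = dY %*% t(cache$cols), b = rowSums(dY)))
}

## Group normalization --------------------------------------------------------
## X is C x P; channels are split into `groups` contiguous groups and each
## group is normalized over its full (channels x positions) block.

init_groupnorm <- function(C) list(g = rep(1, C), b = numeric(C))

groupnorm_fwd <- function(X, p, groups) {
  C <- nrow(X)
  assert_that(C %% groups == 0L, "groups must divide channel count")
  per <- C %/% groups
  xhat <- X
  sds <- numeric(groups)
  for (g in seq_len(groups)) {
    rows <- (g - 1L) * per + seq_len(per)
    blk <- X[rows, , drop = FALSE]
    mu <- mean(blk)
    v <- mean((blk - mu)^2)
    sds[g] <- sqrt(v + .ln_eps)
    xhat[rows, ] <- (blk - mu) / sds[g]
  }
  out <- xhat * p$g + p$b                 # per-channel affine (recycled cols)
  list(out = out, cache = list(xhat = xhat, sds = sds, groups = groups, per = per))
}

groupnorm_bwd <- function(dY, p, cache) {
  xhat <- cache$xhat
  dxhat <- dY * p$g
  dX <- dxhat
  for (g in seq_len(cache$groups)) {
    rows <- (g - 1L) * cache$per + seq_len(cache$per)
    dh <- dxhat[rows, , drop = FALSE]
    xh <- xhat[rows, , drop = FALSE]
    m1 <- mean(dh)
    m2 <- mean(dh * xh)
    dX[rows, ] <- (dh - m1 - xh * m2) / cache$sds[g]
  }
  list(dX = dX,
       grads = list(g = rowSums(dY * xhat), b = rowSums(dY)))
}

## Residual stack -------------------------------------------------------------
## Three repetitions of conv -> groupnorm -> ReLU with one additive skip
## around the whole stack (the smallest structure consistent with
## "convolution, activation, normalization, residual connection" stacks).

init_resblock <- function(C, k_taps, sd = 0.02) {
  lapply(1:3, function(i) list(conv = init_conv(C, C, k_taps, sd),
                               gn = init_groupnorm(C)))
}

resblock_fwd <- function(X, p, nb, groups) {
  Y <- X
  caches <- vector("list", 3L)
  for (s in 1:3) {
    cv <- conv_fwd(Y, p[[s]]$conv, nb)
    gn <- groupnorm_fwd(cv$out, p[[s]]$gn, groups)
    caches[[s]] <- list(conv = cv$cache, gn = gn$cache, pre_relu = gn$out)
    Y <- relu_fwd(gn$out)
  }
  list(out = X + Y, cache = caches)
}

resblock_bwd <- function(dOut, p, cache) {
  dY <- dOut
  grads <- vector("list", 3L)
  for (s in 3:1) {
    dpre <- relu_bwd(dY, cache[[s]]$pre_relu)
    gn <- groupnorm_bwd(dpre, p[[s]]$gn, cache[[s]]$gn)
    cv <- conv_bwd(gn$dX, p[[s]]$conv, cache[[s]]$conv)
    grads[[s]] <- list(conv = cv$grads, gn = gn$grads)
    dY <- cv$dX
  }
  list(dX = dOut + dY, grads = grads)
}
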
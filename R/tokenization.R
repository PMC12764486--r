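## Cube embedding, token masking, and fixed sinusoidal positional encodings.

#' Cube grid specification
#'
#' Fixes how a `T x C x H x W` clip is partitioned into non-overlapping
#' space-time cubes of size `tau x h x w` (times C channels), each of which
#' becomes one token. Grid extents are `t_bar = T/tau`, `h_bar = H/h`,
#' `w_bar = W/w`; the token sequence length is
#' `L_seq = t_bar * h_bar * w_bar`. Tokens are ordered in a fixed t-major
#' raster (t, then h, then w).
#'
#' @param T,H,W clip dimensions.
#' @param tau temporal stride (frames per cube).
#' @param h,w spatial strides (pixels per cube).
#' @param d_model embedding width.
#' @return an object of class `cube_grid_spec`.
#' @export
cube_grid_spec <- function(T = 16L, H = 224L, W = 224L,
                           tau = 2L, h = 16L, w = 16L, d_model = 768L) {
  for (v in list(T, H, W, tau, h, w, d_model)) {
    assert_that(is_count(v), "grid dimensions must be positive integers")
  }
  if (T %% tau != 0L) stop2(sprintf("configuration error: tau=%d does not divide T=%d", tau, T))
  if (H %% h != 0L) stop2(sprintf("configuration error: h=%d does not divide H=%d", h, H))
  if (W %% w != 0L) stop2(sprintf("configuration error: w=%d does not divide W=%d", w, W))
  structure(list(T = as.integer(T), H = as.integer(H), W = as.integer(W),
                 tau = as.integer(tau), h = as.integer(h), w = as.integer(w),
                 t_bar = as.integer(T %/% tau), h_bar = as.integer(H %/% h),
                 w_bar = as.integer(W %/% w), d_model = as.integer(d_model)),
            class = "cube_grid_spec")
}

#' @export
print.cube_grid_spec <- function(x, ...) {
  cat(sprintf("<cube_grid_spec> %dx%dx%d clip, cubes %dx%dx%d -> grid %dx%dx%d (L_seq=%d), d_model=%d\n",
              x$T, x$H, x$W, x$tau, x$h, x$w, x$t_bar, x$h_bar, x$w_bar,
              grid_L(x), x$d_model))
  invisible(x)
}

grid_L <- function(grid) grid$t_bar * grid$h_bar * grid$w_bar

#' Token sequence length for a cube embedding
#'
#' `L_seq = (T/tau) * (H/h) * (W/w)`; dimensions must divide exactly (no
#' implicit padding).
#'
#' @param T,tau,H,h,W,w clip dimensions and cube strides.
#' @return integer sequence length.
#' @export
seq_length <- function(T, tau, H, h, W, w) {
  grid_L(cube_grid_spec(T = T, H = H, W = W, tau = tau, h = h, w = w, d_model = 8L))
}

## Raster bijection: 1-based token index i <-> 0-based (t, h, w) coordinates,
## t-major then h then w.
token_coords <- function(grid) {
  L <- grid_L(grid)
  i0 <- 0:(L - 1)
  w <- i0 %% grid$w_bar
  h <- (i0 %/% grid$w_bar) %% grid$h_bar
  t <- i0 %/% (grid$w_bar * grid$h_bar)
  cbind(t = t, h = h, w = w)
}

token_index <- function(grid, t, h, w) {
  as.integer((t * grid$h_bar + h) * grid$w_bar + w + 1L)
}

# Linear pixel indices (into the T*C*H*W array, R column-major order with
# dim c(T, C, H, W)) for every cube, as an L x (tau*h*w*C) integer matrix.
# Inner (per-cube) ordering is fixed: channel fastest, then dt, dh, dw.
cube_pixel_index <- function(grid) {
  key <- paste("cpi", grid$T, grid$H, grid$W, grid$tau, grid$h, grid$w)
  cached <- .cache_get(key)
  if (!is.null(cached)) return(cached)
  co <- token_coords(grid)
  L <- nrow(co)
  inner <- expand.grid(c = 0:2, dt = 0:(grid$tau - 1),
                       dh = 0:(grid$h - 1), dw = 0:(grid$w - 1))
  P <- nrow(inner)
  idx <- matrix(0L, L, P)
  dimT <- grid$T; dimC <- 3L; dimH <- grid$H
  for (i in seq_len(L)) {
    tt <- co[i, "t"] * grid$tau + inner$dt
    hh <- co[i, "h"] * grid$h + inner$dh
    ww <- co[i, "w"] * grid$w + inner$dw
    idx[i, ] <- as.integer(1L + tt + dimT * (inner$c + dimC * (hh + dimH * ww)))
  }
  .cache_set(key, idx)
  idx
}

# tiny package-local cache for index maps
.efc_cache <- new.env(parent = emptyenv())
.cache_get <- function(key) .efc_cache[[key]]
.cache_set <- function(key, val) assign(key, val, envir = .efc_cache)

#' Gather a clip's pixels into per-cube rows
#'
#' Returns an `L_seq x (tau*h*w*C)` matrix: row i holds the raveled pixels
#' of cube i in the fixed raster/inner ordering. [cube_scatter()] is its
#' exact inverse.
#'
#' @param pixels clip pixel array `T x 3 x H x W`.
#' @param grid a [cube_grid_spec()].
#' @return numeric matrix `L_seq x cube_dim`.
#' @export
cube_gather <- function(pixels, grid) {
  d <- dim(pixels)
  assert_that(identical(as.integer(d), c(grid$T, 3L, grid$H, grid$W)),
              "configuration error: clip shape does not match grid spec")
  idx <- cube_pixel_index(grid)
  matrix(pixels[as.vector(idx)], nrow = nrow(idx))
}

#' Scatter per-cube rows back into a clip array
#' @param rows matrix `L_seq x cube_dim` as produced by [cube_gather()].
#' @param grid a [cube_grid_spec()].
#' @return pixel array `T x 3 x H x W`.
#' @export
cube_scatter <- function(rows, grid) {
  idx <- cube_pixel_index(grid)
  assert_that(identical(dim(rows), dim(idx)), "rows shape mismatch")
  out <- array(0, dim = c(grid$T, 3L, grid$H, grid$W))
  out[as.vector(idx)] <- as.vector(rows)
  out
}

#' Cube-embed a clip into a token sequence
#'
#' Every `tau x h x w` space-time cube (all 3 channels) is raveled and
#' mapped through one shared affine projection to `d_model` features.
#'
#' @param clip a [video_clip()] (or a bare pixel array).
#' @param grid a [cube_grid_spec()].
#' @param weights list with `W` (`cube_dim x d_model`) and `b` (`d_model`);
#'   see [init_cube_embed()].
#' @return list of class `token_sequence`: `tokens` (`L_seq x d_model`),
#'   `grid`, `frame_indices`.
#' @export
cube_embed <- function(clip, grid, weights) {
  pixels <- if (inherits(clip, "video_clip")) clip$pixels else clip
  fi <- if (inherits(clip, "video_clip")) clip$frame_indices else seq_len(grid$T) - 1L
  X <- cube_gather(pixels, grid)
  assert_that(nrow(weights$W) == ncol(X) && ncol(weights$W) == grid$d_model,
              "configuration error: embedding weight shape mismatch")
  tok <- X %*% weights$W
  tok <- sweep(tok, 2L, weights$b, "+")
  structure(list(tokens = tok, grid = grid, frame_indices = fi),
            class = "token_sequence")
}

#' Initialize cube-embedding weights
#' @param grid a [cube_grid_spec()].
#' @param seed integer seed.
#' @return list with `W` and `b`.
#' @export
init_cube_embed <- function(grid, seed = 1L) {
  cube_dim <- grid$tau * grid$h * grid$w * 3L
  with_seed(seed, list(
    W = matrix(stats::rnorm(cube_dim * grid$d_model, sd = 0.02),
               cube_dim, grid$d_model),
    b = numeric(grid$d_model)))
}

#' Draw a random token mask
#'
#' Uniform subset without replacement of size `floor(rho * L_seq)`,
#' reproducible under `seed`.
#'
#' @param L_seq sequence length.
#' @param rho mask ratio in `[0, 1)`.
#' @param seed integer seed.
#' @return object of class `mask_spec` with sorted integer `masked`,
#'   `visible`, plus `L_seq`, `rho`, `seed`.
#' @export
make_mask <- function(L_seq, rho, seed = 1L) {
  assert_that(is_count(L_seq), "L_seq must be a positive integer")
  if (!(is.numeric(rho) && length(rho) == 1L && rho >= 0 && rho < 1)) {
    stop2("parameter error: mask ratio must lie in [0, 1)")
  }
  n_mask <- floor(rho * L_seq)
  masked <- if (n_mask > 0) {
    sort(with_seed(seed, sample.int(L_seq, n_mask)))
  } else integer(0)
  visible <- setdiff(seq_len(L_seq), masked)
  structure(list(masked = as.integer(masked), visible = as.integer(visible),
                 L_seq = as.integer(L_seq), rho = rho, seed = as.integer(seed)),
            class = "mask_spec")
}

## ---------------------------------------------------------------------------
## Fixed sinusoidal positional encodings

# Standard 1D sinusoidal encoding for arbitrary (possibly sparse) positions.
# Returns length(pos) x d, channels alternating sin/cos over geometric
# frequencies; odd d gets a zero-padded final channel.
sinusoid_encoding <- function(pos, d) {
  n_pair <- d %/% 2L
  E <- matrix(0, length(pos), d)
  if (n_pair > 0) {
    ex <- (0:(n_pair - 1)) / max(n_pair, 1L)
    freq <- 1 / (10000^ex)
    arg <- outer(pos, freq)
    E[, seq_len(n_pair) * 2L - 1L] <- sin(arg)
    E[, seq_len(n_pair) * 2L] <- cos(arg)
  }
  E
}

#' Fixed 3D sinusoidal positional encoding over a cube grid
#'
#' `d_model` is split into three near-equal even-width blocks encoding the
#' t, h and w grid coordinates with standard sinusoids; remainder channels
#' are zero. Deterministic, bounded in `[-1, 1]`, and injective over grid
#' positions for `d_model >= 6`.
#'
#' @param grid a [cube_grid_spec()].
#' @return matrix `L_seq x d_model`.
#' @export
positional_encoding_3d <- function(grid) {
  d <- grid$d_model
  d_axis <- (d %/% 6L) * 2L               # even block per axis
  co <- token_coords(grid)
  E <- matrix(0, nrow(co), d)
  if (d_axis > 0) {
    E[, seq_len(d_axis)] <- sinusoid_encoding(co[, "t"], d_axis)
    E[, d_axis + seq_len(d_axis)] <- sinusoid_encoding(co[, "h"], d_axis)
    E[, 2L * d_axis + seq_len(d_axis)] <- sinusoid_encoding(co[, "w"], d_axis)
  }
  E
}
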
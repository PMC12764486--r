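## Attention-rollout saliency for encoders without a CLS token: roll the
## per-layer attention maps, pick one token's row, reshape it onto the cube
## grid, and upsample each temporal slab to frame resolution.

#' Attention rollout
#'
#' Multiplies residual-adjusted attention matrices layer by layer:
#' `R <- normalize(0.5 * (A_l + I)) %*% R`, starting from the identity.
#' Every input row must be a probability distribution; the result is again
#' row-stochastic.
#'
#' @param per_layer_attention list of `L_seq x L_seq` row-stochastic
#'   matrices, one per layer, in layer order (e.g. from
#'   [encode_visible()] with `want_attention = TRUE`).
#' @return rolled attention matrix `L_seq x L_seq`.
#' @export
attention_rollout <- function(per_layer_attention) {
  assert_that(length(per_layer_attention) >= 1L, "need at least one layer")
  L <- nrow(per_layer_attention[[1]])
  R <- diag(L)
  for (A in per_layer_attention) {
    assert_that(is.matrix(A) && all(dim(A) == L), "attention shape mismatch")
    assert_that(all(A >= -1e-9) && max(abs(rowSums(A) - 1)) < 1e-6,
                "contract error: attention rows must be probability distributions")
    Ab <- 0.5 * (A + diag(L))
    Ab <- Ab / rowSums(Ab)
    R <- Ab %*% R
  }
  R
}

#' Saliency map from one rolled-attention row
#'
#' Row `i` of the rolled attention is reshaped onto the `t_bar x h_bar x
#' w_bar` grid by the fixed raster bijection; each temporal slab is
#' bilinearly upsampled to `H x W` and copied to its `tau` source frames.
#' Per-frame maps are max-normalized to `[0, 1]`.
#'
#' @param rolled rolled attention matrix from [attention_rollout()].
#' @param i 1-based query token index.
#' @param grid a [cube_grid_spec()].
#' @return object of class `saliency_map`: `grid_saliency` (array `t_bar x
#'   h_bar x w_bar`), `frames` (array `T x H x W`, normalized per frame).
#' @export
row_saliency <- function(rolled, i, grid) {
  L <- grid_L(grid)
  assert_that(i >= 1 && i <= L, "token index out of range")
  row <- rolled[i, ]
  co <- token_coords(grid)
  gs <- array(0, dim = c(grid$t_bar, grid$h_bar, grid$w_bar))
  gs[cbind(co[, "t"] + 1L, co[, "h"] + 1L, co[, "w"] + 1L)] <- row
  Wh <- bilinear_weights(grid$h_bar, grid$H)
  Ww <- bilinear_weights(grid$w_bar, grid$W)
  frames <- array(0, dim = c(grid$T, grid$H, grid$W))
  for (tt in seq_len(grid$t_bar)) {
    slab <- matrix(gs[tt, , ], grid$h_bar, grid$w_bar)
    up <- Wh %*% slab %*% t(Ww)
    mx <- max(up)
    if (mx > 0) up <- up / mx
    for (k in seq_len(grid$tau)) frames[(tt - 1L) * grid$tau + k, , ] <- up
  }
  structure(list(grid_saliency = gs, frames = frames, token = i),
            class = "saliency_map")
}

#' Overlay saliency maps on clip frames
#'
#' Blends each frame with a red heat layer: `out = (1 - s) * frame + s *
#' red`, so zero saliency reproduces the raw frame exactly. Writes one PNG
#' per frame plus an AVI of the overlay; outputs are deterministic given
#' identical inputs.
#'
#' @param clip a [video_clip()].
#' @param maps a `saliency_map` from [row_saliency()].
#' @param out_dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return character vector of written files, invisibly.
#' @export
overlay <- function(clip, maps, out_dir, prefix = "saliency") {
  d <- dim(clip$pixels)
  assert_that(all(dim(maps$frames) == c(d[1], d[3], d[4])),
              "saliency maps do not match clip shape")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  over <- clip$pixels
  red <- c(1, 0.1, 0.1)
  files <- character(d[1])
  for (f in seq_len(d[1])) {
    s <- maps$frames[f, , ]
    for (c in 1:3) {
      over[f, c, , ] <- (1 - s) * clip$pixels[f, c, , ] + s * red[c]
    }
    img <- array(0, dim = c(d[3], d[4], 3L))
    for (c in 1:3) img[, , c] <- over[f, c, , ]
    files[f] <- file.path(out_dir, sprintf("%s_frame%03d.png", prefix, f))
    png::writePNG(img, files[f])
  }
  avi <- file.path(out_dir, paste0(prefix, ".avi"))
  write_video(clip01(over), avi)
  invisible(c(files, avi))
}

#' End-to-end saliency for a clip
#'
#' Runs the encoder over the full (unmasked) token sequence, rolls out its
#' attention, and extracts the saliency of one query token.
#'
#' @param model an `mae_model` (or the `encoder_model` of a fitted model).
#' @param clip a [video_clip()].
#' @param token `"center"` (default), `"random:<seed>"`, or a 1-based index.
#' @return list with `saliency` (a `saliency_map`), `rolled`, and the
#'   resolved `token` index.
#' @export
explain_clip <- function(model, clip, token = "center") {
  enc <- encode_clip(model, clip, want_attention = TRUE)
  rolled <- attention_rollout(enc$attention)
  grid <- model$grid
  i <- resolve_token(token, grid)
  list(saliency = row_saliency(rolled, i, grid), rolled = rolled, token = i)
}

resolve_token <- function(token, grid) {
  L <- grid_L(grid)
  if (is.numeric(token)) {
    as.integer(token)
  } else if (identical(token, "center")) {
    token_index(grid, grid$t_bar %/% 2L, grid$h_bar %/% 2L, grid$w_bar %/% 2L)
  } else if (grepl("^random:", token)) {
    seed <- as.integer(sub("^random:", "", token))
    with_seed(seed, sample.int(L, 1L))
  } else stop2("token must be 'center', 'random:<seed>', or an index")
}
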
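## Spatial-Temporal Fusion Network: a joint pathway (3D conv residual block
## over the full token grid) and a disjoint pathway (per-frame 2D processing,
## learnable pooling to one vector per temporal slab, sparse frame-index
## positional encodings), each pooled by gated self-attention, concatenated
## into a fused 2*d_model representation.

#' Gated attention pooling parameters
#'
#' Three matrices `w` (`L x 1`), `U`, `V` (`L x d_model`), `L = 1024` by
#' default. Scores are `w' (tanh(V x) * sigmoid(U x))`, softmax-normalized
#' into pooling weights.
#'
#' @param d_model feature width of the pooled vectors.
#' @param L gating hidden width.
#' @param sd init scale.
#' @return parameter list with `w`, `U`, `V`.
#' @export
init_gated_attention <- function(d_model, L = 1024L, sd = 0.02) {
  list(w = matrix(stats::rnorm(L, sd = sd), L, 1L),
       U = matrix(stats::rnorm(L * d_model, sd = sd), L, d_model),
       V = matrix(stats::rnorm(L * d_model, sd = sd), L, d_model))
}

#' Gated self-attention pooling
#'
#' Pools `K` instance vectors into one: each instance `x_k` receives score
#' `w' (tanh(V x_k) * sigmoid(U x_k))`; weights are the softmax of the
#' scores (positive, summing to one), and the pooled vector is the weighted
#' sum — hence it always lies in the convex hull of the inputs and is
#' invariant to permuting them.
#'
#' @param X matrix `K x d_model` of instance vectors (rows).
#' @param params from [init_gated_attention()].
#' @return list with `pooled` (length `d_model`), `weights` (length `K`),
#'   and `cache` for the backward pass.
#' @export
gated_attention_pool <- function(X, params) {
  assert_that(nrow(X) >= 1L, "need at least one instance vector")
  Tm <- tanh(X %*% t(params$V))             # K x L
  Sm <- 1 / (1 + exp(-(X %*% t(params$U))))
  G <- Tm * Sm
  score <- as.vector(G %*% params$w)
  a <- softmax_vec(score)
  pooled <- as.vector(t(X) %*% a)
  list(pooled = pooled, weights = a,
       cache = list(X = X, Tm = Tm, Sm = Sm, G = G, a = a))
}

gated_attention_bwd <- function(dpooled, params, cache) {
  X <- cache$X; a <- cache$a
  da <- as.vector(X %*% dpooled)
  dX <- outer(a, dpooled)
  dscore <- a * (da - sum(da * a))
  dG <- dscore %*% t(params$w)              # K x L
  dw <- t(cache$G) %*% dscore
  dTm <- dG * cache$Sm
  dSm <- dG * cache$Tm
  pre_t <- (1 - cache$Tm^2) * dTm
  pre_s <- cache$Sm * (1 - cache$Sm) * dSm
  dV <- t(pre_t) %*% X
  dU <- t(pre_s) %*% X
  dX <- dX + pre_t %*% params$V + pre_s %*% params$U
  list(dX = dX, grads = list(w = dw, U = dU, V = dV))
}

#' Initialize an STF-Net
#'
#' @param grid a [cube_grid_spec()].
#' @param L_gate gated-attention hidden width (1024 by default, shared by
#'   both pathways).
#' @param groups group-normalization groups inside residual blocks (must
#'   divide `d_model`).
#' @param seed integer seed.
#' @return object of class `stf_net`.
#' @export
init_stf <- function(grid, L_gate = 1024L, groups = NULL, seed = 1L) {
  d <- grid$d_model
  if (is.null(groups)) groups <- if (d %% 8L == 0L) 8L else 1L
  assert_that(d %% groups == 0L, "groups must divide d_model")
  spatial <- grid$h_bar * grid$w_bar
  params <- with_seed(seed, list(
    res3d = init_resblock(d, 27L),
    gate_joint = init_gated_attention(d, L_gate),
    res2d = init_resblock(d, 9L),
    lk = list(W = matrix(stats::rnorm(d * d * spatial, sd = 0.02), d, d * spatial),
              b = numeric(d)),
    fc1 = init_linear(d, d),
    fc2 = init_linear(d, d),
    gate_disjoint = init_gated_attention(d, L_gate)
  ))
  structure(list(params = params, grid = grid, groups = as.integer(groups),
                 L_gate = as.integer(L_gate),
                 pos_enc3d = positional_encoding_3d(grid)),
            class = "stf_net")
}

## Joint pathway --------------------------------------------------------------

joint_forward <- function(stf, tokens) {
  g <- stf$grid
  assert_that(nrow(tokens) == grid_L(g), "contract error: grid mismatch")
  Xg <- t(tokens + stf$pos_enc3d)           # d x L feature map
  nb <- conv_index_3d(g$t_bar, g$h_bar, g$w_bar)
  rb <- resblock_fwd(Xg, stf$params$res3d, nb, stf$groups)
  seq <- t(rb$out)                          # L x d, raster order preserved
  gp <- gated_attention_pool(seq, stf$params$gate_joint)
  list(out = gp$pooled, weights = gp$weights,
       cache = list(rb = rb$cache, gp = gp$cache))
}

joint_backward <- function(stf, dout, cache) {
  g <- stf$grid
  gb <- gated_attention_bwd(dout, stf$params$gate_joint, cache$gp)
  nb <- conv_index_3d(g$t_bar, g$h_bar, g$w_bar)
  rbb <- resblock_bwd(t(gb$dX), stf$params$res3d, cache$rb)
  list(dtokens = t(rbb$dX),
       grads = list(res3d = rbb$grads, gate_joint = gb$grads))
}

#' Joint space-time fusion pathway
#'
#' Reshapes the token sequence onto its 3D grid, adds dense 3D positional
#' encodings, applies one 3D-convolutional residual block, flattens, and
#' pools with gated attention.
#'
#' @param stf an [init_stf()] network.
#' @param tokens a `token_sequence` (full, unmasked) or `L_seq x d_model`
#'   matrix.
#' @return list with `out` (length `d_model`) and `weights` (`L_seq`).
#' @export
joint_pathway <- function(stf, tokens) {
  tk <- if (inherits(tokens, "token_sequence")) tokens$tokens else tokens
  r <- joint_forward(stf, tk)
  r[c("out", "weights")]
}

## Disjoint pathway -----------------------------------------------------------

# Average consecutive groups of tau frame-index encodings down to t_bar rows.
group_average_encodings <- function(E, tau) {
  Tn <- nrow(E)
  assert_that(Tn %% tau == 0L, "configuration error: tau must divide T")
  grp <- rep(seq_len(Tn %/% tau), each = tau)
  rowsum(E, grp) / tau
}

disjoint_forward <- function(stf, tokens, frame_indices) {
  g <- stf$grid
  assert_that(nrow(tokens) == grid_L(g), "contract error: grid mismatch")
  if (length(frame_indices) != g$T) {
    stop2(sprintf("configuration error: %d frame indices for T=%d",
                  length(frame_indices), g$T))
  }
  d <- g$d_model
  spatial <- g$h_bar * g$w_bar
  nb <- conv_index_2d(g$h_bar, g$w_bar)
  Xg <- t(tokens)                            # d x L

  slab_caches <- vector("list", g$t_bar)
  cols <- matrix(0, d * spatial, g$t_bar)
  for (tt in seq_len(g$t_bar)) {
    sel <- (tt - 1L) * spatial + seq_len(spatial)
    rb <- resblock_fwd(Xg[, sel, drop = FALSE], stf$params$res2d, nb, stf$groups)
    slab_caches[[tt]] <- rb$cache
    cols[, tt] <- as.vector(rb$out)
  }
  Yt <- t(stf$params$lk$W %*% cols + stf$params$lk$b)   # t_bar x d

  E <- sinusoid_encoding(frame_indices, d)              # T x d
  Eavg <- group_average_encodings(E, g$tau)             # t_bar x d
  z1 <- linear_fwd(Eavg, stf$params$fc1)
  h1 <- relu_fwd(z1)
  S <- linear_fwd(h1, stf$params$fc2)                   # t_bar x d
  seq <- Yt + S
  gp <- gated_attention_pool(seq, stf$params$gate_disjoint)
  list(out = gp$pooled, weights = gp$weights,
       cache = list(slabs = slab_caches, cols = cols, Eavg = Eavg,
                    z1 = z1, h1 = h1, gp = gp$cache))
}

disjoint_backward <- function(stf, dout, cache) {
  g <- stf$grid
  d <- g$d_model
  spatial <- g$h_bar * g$w_bar
  gb <- gated_attention_bwd(dout, stf$params$gate_disjoint, cache$gp)
  dseq <- gb$dX                                        # t_bar x d

  f2 <- linear_bwd(dseq, cache$h1, stf$params$fc2)
  dz1 <- relu_bwd(f2$dX, cache$z1)
  f1 <- linear_bwd(dz1, cache$Eavg, stf$params$fc1)

  dYt <- t(dseq)                                       # d x t_bar
  dlk_W <- dYt %*% t(cache$cols)
  dlk_b <- rowSums(dYt)
  dcols <- t(stf$params$lk$W) %*% dYt                  # (d*spatial) x t_bar

  dtok <- matrix(0, d, grid_L(g))
  res_grads <- NULL
  for (tt in seq_len(g$t_bar)) {
    sel <- (tt - 1L) * spatial + seq_len(spatial)
    dslab <- matrix(dcols[, tt], d, spatial)
    rbb <- resblock_bwd(dslab, stf$params$res2d, cache$slabs[[tt]])
    dtok[, sel] <- rbb$dX
    res_grads <- if (is.null(res_grads)) rbb$grads else tree_add(res_grads, rbb$grads)
  }
  list(dtokens = t(dtok),
       grads = list(res2d = res_grads,
                    lk = list(W = dlk_W, b = dlk_b),
                    fc1 = f1$grads, fc2 = f2$grads,
                    gate_disjoint = gb$grads))
}

#' Disjoint space-time fusion pathway
#'
#' Treats the token grid as `t_bar` stacked 2D maps, applies a 2D residual
#' block and a large-kernel convolution with kernel = stride = grid extent
#' (a learnable pooling) to obtain one vector per temporal slab, adds
#' learnable sparse positional encodings built from the clip's original
#' frame indices (sinusoids averaged in groups of `tau`, then an FC head),
#' and pools the `t_bar` vectors with gated attention.
#'
#' @param stf an [init_stf()] network.
#' @param tokens a `token_sequence` or `L_seq x d_model` matrix.
#' @param frame_indices length-`T` original frame indices (taken from the
#'   `token_sequence` if not given).
#' @return list with `out` (length `d_model`) and `weights` (`t_bar`).
#' @export
disjoint_pathway <- function(stf, tokens, frame_indices = NULL) {
  if (inherits(tokens, "token_sequence")) {
    if (is.null(frame_indices)) frame_indices <- tokens$frame_indices
    tokens <- tokens$tokens
  }
  assert_that(!is.null(frame_indices), "frame_indices required")
  r <- disjoint_forward(stf, tokens, frame_indices)
  r[c("out", "weights")]
}

## Fusion ---------------------------------------------------------------------

stf_forward <- function(stf, tokens, frame_indices) {
  j <- joint_forward(stf, tokens)
  dj <- disjoint_forward(stf, tokens, frame_indices)
  list(fused = c(j$out, dj$out), joint = j$out, disjoint = dj$out,
       cache = list(j = j$cache, dj = dj$cache))
}

stf_backward <- function(stf, dfused, cache) {
  d <- stf$grid$d_model
  jb <- joint_backward(stf, dfused[seq_len(d)], cache$j)
  db <- disjoint_backward(stf, dfused[d + seq_len(d)], cache$dj)
  list(dtokens = jb$dtokens + db$dtokens,
       grads = c(jb$grads, db$grads))
}

#' Fuse a token sequence through both pathways
#'
#' @param stf an [init_stf()] network.
#' @param tokens a `token_sequence` from [cube_embed()] (full, unmasked) or
#'   a matrix plus `frame_indices`.
#' @param frame_indices length-`T` original frame indices.
#' @return object of class `fused_representation` with `joint_vec`,
#'   `disjoint_vec`, and `fused` (their concatenation, width `2 * d_model`).
#' @export
fuse <- function(stf, tokens, frame_indices = NULL) {
  if (inherits(tokens, "token_sequence")) {
    if (is.null(frame_indices)) frame_indices <- tokens$frame_indices
    tokens <- tokens$tokens
  }
  r <- stf_forward(stf, tokens, frame_indices)
  structure(list(joint_vec = r$joint, disjoint_vec = r$disjoint,
                 fused = r$fused),
            class = "fused_representation")
}
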
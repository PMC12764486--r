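## Asymmetric masked video auto-encoder: a deep joint space-time attention
## encoder that sees only visible tokens, a shallow decoder over the full
## token grid, pixel-space reconstruction loss over masked cubes, and the
## pre-training loop.

#' Encoder / decoder architecture configuration
#'
#' Defaults follow the reference architecture: a ViT-Base style encoder with
#' 12 attention layers and `d_model = 768`, and a shallow 4-layer decoder.
#' Head count and MLP ratio follow the ViT-Base convention (12 heads, ratio
#' 4); decoder width defaults to `d_model / 2`.
#'
#' @param depth encoder attention layers.
#' @param d_model encoder feature width.
#' @param heads encoder attention heads (`d_model` divisible by `heads`).
#' @param mlp_ratio MLP hidden width multiplier.
#' @param decoder_depth decoder attention layers.
#' @param decoder_width decoder feature width (default `d_model / 2`).
#' @param decoder_heads decoder attention heads.
#' @return object of class `encoder_config`.
#' @export
encoder_config <- function(depth = 12L, d_model = 768L, heads = 12L,
                           mlp_ratio = 4, decoder_depth = 4L,
                           decoder_width = NULL, decoder_heads = 8L) {
  if (is.null(decoder_width)) decoder_width <- max(8L, d_model %/% 2L)
  assert_that(is_count(depth) && is_count(decoder_depth), "depths must be >= 1")
  assert_that(d_model %% heads == 0L, "d_model must be divisible by heads")
  assert_that(decoder_width %% decoder_heads == 0L,
              "decoder_width must be divisible by decoder_heads")
  structure(list(depth = as.integer(depth), d_model = as.integer(d_model),
                 heads = as.integer(heads), mlp_ratio = mlp_ratio,
                 decoder_depth = as.integer(decoder_depth),
                 decoder_width = as.integer(decoder_width),
                 decoder_heads = as.integer(decoder_heads)),
            class = "encoder_config")
}

#' Initialize a masked auto-encoder model
#'
#' @param grid a [cube_grid_spec()]; `grid$d_model` must equal
#'   `cfg$d_model`.
#' @param cfg an [encoder_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `mae_model` holding all parameters plus the fixed
#'   sinusoidal positional encodings for encoder and decoder.
#' @export
init_mae <- function(grid, cfg = encoder_config(), seed = 1L) {
  assert_that(grid$d_model == cfg$d_model,
              "configuration error: grid d_model differs from encoder d_model")
  cube_dim <- grid$tau * grid$h * grid$w * 3L
  params <- with_seed(seed, list(
    embed = list(W = matrix(stats::rnorm(cube_dim * cfg$d_model, sd = 0.02),
                            cube_dim, cfg$d_model),
                 b = numeric(cfg$d_model)),
    encoder = init_transformer(cfg$depth, cfg$d_model, cfg$heads, cfg$mlp_ratio),
    enc_to_dec = init_linear(cfg$d_model, cfg$decoder_width),
    mask_token = stats::rnorm(cfg$decoder_width, sd = 0.02),
    decoder = init_transformer(cfg$decoder_depth, cfg$decoder_width,
                               cfg$decoder_heads, cfg$mlp_ratio),
    to_pixels = init_linear(cfg$decoder_width, cube_dim)
  ))
  dec_grid <- grid
  dec_grid$d_model <- cfg$decoder_width
  structure(list(params = params, grid = grid, cfg = cfg, seed = as.integer(seed),
                 pos_enc = positional_encoding_3d(grid),
                 dec_pos_enc = positional_encoding_3d(dec_grid)),
            class = "mae_model")
}

#' Encode the visible tokens of a masked sequence
#'
#' Only visible tokens (plus their positional encodings) enter the encoder;
#' masked-token content cannot influence the output (the information barrier
#' that makes high-ratio masking cheap: encoder cost scales with
#' `(1 - rho) * L_seq`).
#'
#' @param model an [init_mae()] model.
#' @param tokens a `token_sequence` from [cube_embed()].
#' @param mask a [make_mask()] spec with matching `L_seq`.
#' @param want_attention also return per-layer head-averaged attention.
#' @return list with `reps` (`|visible| x d_model`), `cache`, and
#'   optionally `attention`.
#' @export
encode_visible <- function(model, tokens, mask, want_attention = FALSE) {
  L <- grid_L(model$grid)
  assert_that(nrow(tokens$tokens) == L, "token sequence length mismatch")
  assert_that(mask$L_seq == L,
              "contract error: mask L_seq does not match token sequence")
  X <- tokens$tokens + model$pos_enc
  Xv <- X[mask$visible, , drop = FALSE]
  tf <- transformer_fwd(Xv, model$params$encoder, model$cfg$heads,
                        want_attention = want_attention)
  list(reps = tf$out, cache = tf$cache, attention = tf$attention)
}

#' Decode a full clip from visible representations
#'
#' Projects encoder outputs to the decoder width, inserts the learned mask
#' token at every masked index, adds full-grid positional encodings, runs
#' the shallow decoder, and maps each token back to its cube's pixels.
#'
#' @param model an [init_mae()] model.
#' @param visible_reps matrix `|visible| x d_model` from [encode_visible()].
#' @param mask the same [make_mask()] spec.
#' @return list with `pixels` (reconstructed clip `T x 3 x H x W`),
#'   `pred_rows` (`L_seq x cube_dim`), and `cache`.
#' @export
decode_full <- function(model, visible_reps, mask) {
  assert_that(nrow(visible_reps) == length(mask$visible),
              "contract error: visible_reps length does not match mask")
  p <- model$params
  L <- grid_L(model$grid)
  proj <- linear_fwd(visible_reps, p$enc_to_dec)
  D <- matrix(p$mask_token, L, model$cfg$decoder_width, byrow = TRUE)
  D[mask$visible, ] <- proj
  D <- D + model$dec_pos_enc
  tf <- transformer_fwd(D, p$decoder, model$cfg$decoder_heads)
  rows <- linear_fwd(tf$out, p$to_pixels)
  list(pixels = cube_scatter(rows, model$grid), pred_rows = rows,
       cache = list(proj_in = visible_reps, dec_in = D, tf = tf$cache,
                    dec_out = tf$out))
}

#' Masked reconstruction loss
#'
#' Mean squared pixel error over masked cubes only; visible cubes contribute
#' nothing. With per-cube means this equals the mean squared difference over
#' all pixels belonging to masked cubes.
#'
#' @param V original clip (array or [video_clip()]).
#' @param V_hat reconstructed pixel array of the same shape.
#' @param mask a [make_mask()] spec.
#' @param grid the [cube_grid_spec()].
#' @return scalar loss.
#' @export
reconstruction_loss <- function(V, V_hat, mask, grid) {
  if (inherits(V, "video_clip")) V <- V$pixels
  if (length(mask$masked) == 0L) {
    stop2("undefined-loss error: empty mask set (rho = 0 cannot be trained)")
  }
  tv <- cube_gather(V, grid)
  th <- cube_gather(V_hat, grid)
  diff <- th[mask$masked, , drop = FALSE] - tv[mask$masked, , drop = FALSE]
  mean(diff^2)
}

## Full differentiable pipeline ----------------------------------------------

# Forward pass clip -> loss with all caches needed for the backward pass.
mae_forward <- function(model, clip, mask) {
  pixels <- if (inherits(clip, "video_clip")) clip$pixels else clip
  cubes <- cube_gather(pixels, model$grid)
  tok <- sweep(cubes %*% model$params$embed$W, 2L, model$params$embed$b, "+")
  X <- tok + model$pos_enc
  Xv <- X[mask$visible, , drop = FALSE]
  enc <- transformer_fwd(Xv, model$params$encoder, model$cfg$heads)
  dec <- decode_full(model, enc$out, mask)
  diff <- dec$pred_rows[mask$masked, , drop = FALSE] -
    cubes[mask$masked, , drop = FALSE]
  loss <- mean(diff^2)
  list(loss = loss,
       cache = list(cubes = cubes, Xv = Xv, enc = enc, dec = dec,
                    diff = diff, mask = mask))
}

# Backward pass: returns the gradient tree matching model$params.
mae_backward <- function(model, cache) {
  p <- model$params
  mask <- cache$mask
  L <- grid_L(model$grid)
  cube_dim <- ncol(cache$cubes)

  dRows <- matrix(0, L, cube_dim)
  nM <- length(mask$masked)
  dRows[mask$masked, ] <- 2 * cache$diff / (nM * cube_dim)

  pix_b <- linear_bwd(dRows, cache$dec$cache$dec_out, p$to_pixels)
  dec_b <- transformer_bwd(pix_b$dX, p$decoder, cache$dec$cache$tf)
  dD <- dec_b$dX
  d_mask_token <- colSums(dD[mask$masked, , drop = FALSE])
  proj_b <- linear_bwd(dD[mask$visible, , drop = FALSE],
                       cache$dec$cache$proj_in, p$enc_to_dec)
  enc_b <- transformer_bwd(proj_b$dX, p$encoder, cache$enc$cache)
  dX <- matrix(0, L, model$cfg$d_model)
  dX[mask$visible, ] <- enc_b$dX
  emb_grads <- list(W = t(cache$cubes) %*% dX, b = colSums(dX))

  list(embed = emb_grads, encoder = enc_b$grads, enc_to_dec = proj_b$grads,
       mask_token = d_mask_token, decoder = dec_b$grads,
       to_pixels = pix_b$grads)
}

#' Learning-rate schedule: linear warmup then cosine decay
#'
#' Ramps linearly from `init_lr` to `peak_lr` over the first
#' `warmup_fraction` of steps, then decays along a half cosine from
#' `peak_lr` to `floor_lr` at the final step.
#'
#' @param step current step, `0 <= step <= total_steps`.
#' @param total_steps total optimization steps.
#' @param peak_lr peak learning rate (default `1e-4`).
#' @param warmup_fraction fraction of steps spent warming up (default 5%).
#' @param init_lr warmup starting rate (default `1e-5`).
#' @param floor_lr cosine floor (default 0).
#' @return learning rate.
#' @export
lr_schedule <- function(step, total_steps, peak_lr = 1e-4,
                        warmup_fraction = 0.05, init_lr = 1e-5,
                        floor_lr = 0) {
  assert_that(step >= 0 && step <= total_steps, "step out of range")
  w <- warmup_fraction * total_steps
  if (step <= w && w > 0) {
    init_lr + (peak_lr - init_lr) * step / w
  } else {
    prog <- if (total_steps > w) (step - w) / (total_steps - w) else 1
    floor_lr + (peak_lr - floor_lr) * 0.5 * (1 + cos(pi * prog))
  }
}

#' Pre-training hyperparameter state
#'
#' Defaults mirror the reference setup: AdamW with betas (0.9, 0.95),
#' weight decay 0.05, peak learning rate 1e-4 with 5% linear warmup from
#' 1e-5 and cosine decay, 30 epochs at batch size 8, mask ratio 0.85.
#'
#' @param epochs,batch_size training schedule.
#' @param peak_lr,warmup_fraction,warmup_init_lr,floor_lr learning-rate knobs.
#' @param betas,weight_decay AdamW settings.
#' @param mask_ratio token mask ratio in `(0, 1)`.
#' @param seed integer seed driving shuffling and mask draws.
#' @return object of class `pretrain_state`.
#' @export
pretrain_state <- function(epochs = 30L, batch_size = 8L, peak_lr = 1e-4,
                           warmup_fraction = 0.05, warmup_init_lr = 1e-5,
                           floor_lr = 0, betas = c(0.9, 0.95),
                           weight_decay = 0.05, mask_ratio = 0.85,
                           seed = 1L) {
  assert_that(warmup_fraction > 0 && warmup_fraction < 1,
              "warmup_fraction must lie in (0, 1)")
  assert_that(mask_ratio > 0 && mask_ratio < 1,
              "mask_ratio must lie in (0, 1) for pre-training")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 peak_lr = peak_lr, warmup_fraction = warmup_fraction,
                 warmup_init_lr = warmup_init_lr, floor_lr = floor_lr,
                 betas = betas, weight_decay = weight_decay,
                 mask_ratio = mask_ratio, seed = as.integer(seed)),
            class = "pretrain_state")
}

# Load every training clip referenced by a manifest into memory, sampled and
# resized to the grid's T x H x W.
load_manifest_clips <- function(manifest, grid, split = "train",
                                augment_flip = FALSE, seed = 1L) {
  paths <- unique(manifest$path[manifest$split == split])
  if (length(paths) == 0L) stop2(sprintf("data error: no '%s' clips in manifest", split))
  lapply(seq_along(paths), function(i) {
    raw <- read_video(paths[i])
    clip <- uniform_temporal_sample(raw, grid$T, source_id = paths[i])
    d <- dim(clip$pixels)
    if (d[3] != grid$H || d[4] != grid$W) {
      clip <- resize_and_normalize(clip, grid$H, grid$W)
    }
    if (augment_flip) {
      clip <- random_horizontal_flip(clip, 0.5, seed = derive_seed(seed, paste0("flip", i)))
    }
    clip
  })
}

#' Run masked auto-encoder pre-training
#'
#' @param manifest manifest data frame (see [read_manifest()]); clips in the
#'   `train` split are used.
#' @param grid a [cube_grid_spec()].
#' @param cfg an [encoder_config()].
#' @param state a [pretrain_state()].
#' @param log_path optional CSV path for the (step, lr, loss) log.
#' @param clips optional pre-loaded list of [video_clip()]s, bypassing disk.
#' @return object of class `mae_checkpoint`: the trained model plus the loss
#'   history and all configuration needed to resume or reuse it.
#' @export
run_pretraining <- function(manifest, grid, cfg, state = pretrain_state(),
                            log_path = NULL, clips = NULL) {
  if (is.null(clips)) clips <- load_manifest_clips(manifest, grid, "train")
  n <- length(clips)
  assert_that(n >= 1L, "data error: empty training set")
  model <- init_mae(grid, cfg, seed = derive_seed(state$seed, "init"))
  opt <- adam_init(model$params)
  steps_per_epoch <- ceiling(n / state$batch_size)
  total_steps <- state$epochs * steps_per_epoch
  L <- grid_L(grid)

  history <- data.frame(step = integer(0), lr = numeric(0), loss = numeric(0))
  step <- 0L
  with_seed(derive_seed(state$seed, "train"), {
    for (ep in seq_len(state$epochs)) {
      ord <- sample.int(n)
      for (b in seq_len(steps_per_epoch)) {
        ids <- ord[((b - 1L) * state$batch_size + 1L):min(b * state$batch_size, n)]
        grads <- NULL
        loss_sum <- 0
        for (id in ids) {
          mask <- make_mask(L, state$mask_ratio,
                            seed = sample.int(.Machine$integer.max, 1L))
          fw <- mae_forward(model, clips[[id]], mask)
          bw <- mae_backward(model, fw$cache)
          grads <- if (is.null(grads)) bw else tree_add(grads, bw)
          loss_sum <- loss_sum + fw$loss
        }
        grads <- tree_scale(grads, 1 / length(ids))
        step <- step + 1L
        lr <- lr_schedule(step, total_steps, state$peak_lr,
                          state$warmup_fraction, state$warmup_init_lr,
                          state$floor_lr)
        upd <- adam_step(model$params, grads, opt, lr, state$betas,
                         weight_decay = state$weight_decay)
        model$params <- upd$params
        opt <- upd$state
        history <- rbind(history, data.frame(step = step, lr = lr,
                                             loss = loss_sum / length(ids)))
      }
    }
  })
  if (!is.null(log_path)) utils::write.csv(history, log_path, row.names = FALSE)
  structure(list(model = model, grid = grid, cfg = cfg, state = state,
                 history = history),
            class = "mae_checkpoint")
}

#' Save / load a checkpoint (single-file archive)
#' @param ckpt a checkpoint object.
#' @param path destination file.
#' @return `path` (save) or the checkpoint (load).
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  assert_that(file.exists(path), sprintf("checkpoint not found: %s", path))
  readRDS(path)
}

# Embed + encode a full (unmasked) clip; used by fine-tuning and saliency.
encode_clip <- function(model, clip, want_attention = FALSE) {
  tok <- cube_embed(clip, model$grid, model$params$embed)
  mask0 <- make_mask(grid_L(model$grid), 0)
  encode_visible(model, tok, mask0, want_attention = want_attention)
}
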
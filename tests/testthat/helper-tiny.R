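# Shared fixtures: tiny grid/model constructors and a finite-difference
# gradient checker. Everything is generated in code; no binary fixtures.

tiny_grid <- function(d_model = 64L) {
  cube_grid_spec(T = 8L, H = 32L, W = 32L, tau = 2L, h = 16L, w = 16L,
                 d_model = d_model)
}

tiny_cfg <- function(d_model = 64L) {
  encoder_config(depth = 2L, d_model = d_model, heads = 4L, mlp_ratio = 2,
                 decoder_depth = 1L, decoder_width = 32L, decoder_heads = 4L)
}

# A smaller grid for gradient checks (cheap finite differences).
micro_grid <- function() {
  cube_grid_spec(T = 4L, H = 32L, W = 32L, tau = 2L, h = 16L, w = 16L,
                 d_model = 12L)
}

micro_cfg <- function() {
  encoder_config(depth = 2L, d_model = 12L, heads = 2L, mlp_ratio = 2,
                 decoder_depth = 1L, decoder_width = 8L, decoder_heads = 2L)
}

random_clip <- function(grid, seed = 1L) {
  set.seed(seed)
  video_clip(array(runif(grid$T * 3 * grid$H * grid$W),
                   dim = c(grid$T, 3L, grid$H, grid$W)))
}

tiny_phantom_clip <- function(seed = 1L, T = 8L) {
  lab <- generate_phantom(phantom_params(T_raw = 24L, H = 32L, W = 32L,
                                         seed = seed))
  uniform_temporal_sample(lab$clip$pixels, T)
}

# Compare an analytic gradient tree against central finite differences of
# `loss_fn(params)` at `n_coords` random coordinates.
expect_gradcheck <- function(loss_fn, params, grads, n_coords = 20L,
                             eps = 1e-5, tol = 1e-3) {
  flat <- unlist(params)
  gflat <- unlist(grads)
  idx <- sample(length(flat), min(n_coords, length(flat)))
  num <- vapply(idx, function(i) {
    up <- flat; up[i] <- up[i] + eps
    dn <- flat; dn[i] <- dn[i] - eps
    (loss_fn(utils::relist(up, params)) - loss_fn(utils::relist(dn, params))) /
      (2 * eps)
  }, numeric(1))
  rel <- max(abs(num - gflat[idx]) / pmax(1e-6, abs(num) + abs(gflat[idx])))
  expect_lt(rel, tol)
}

# Global mean/variance/covariance SSIM between two equal-size frames
# (single global window; enough for monotonicity checks on speckle).
global_ssim <- function(a, b) {
  c1 <- (0.01)^2; c2 <- (0.03)^2
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(as.vector(a)); vb <- stats::var(as.vector(b))
  cab <- stats::cov(as.vector(a), as.vector(b))
  ((2 * ma * mb + c1) * (2 * cab + c2)) /
    ((ma^2 + mb^2 + c1) * (va + vb + c2))
}

# 300-clip dataset for the parameter-recovery acceptance test; generated
# once per session and reused if the directory already holds a manifest.
shared_phantom_300 <- function(dir, seed) {
  mp <- file.path(dir, "manifest.csv")
  if (file.exists(mp)) return(read_manifest(mp))
  generate_dataset(300, dir, seed = derive_seed(seed, "data"))
}

# Tiny-profile checkpoint pre-trained on the shared 300-clip dataset's train
# split; cached per session so both parameter-recovery criteria reuse it.
shared_pretrained_tiny <- local({
  env <- new.env()
  function(splits, seed) {
    key <- paste0("ck", seed)
    if (is.null(env[[key]])) {
      env[[key]] <- run_pretraining(
        NULL, tiny_grid(), tiny_cfg(),
        pretrain_state(epochs = 5, batch_size = 8, peak_lr = 1e-3,
                       mask_ratio = 0.85, seed = derive_seed(seed, "pt")),
        clips = splits$train$clips)
    }
    env[[key]]
  }
})

# Dataset cached per test session (generated once, reused across files).
shared_tiny_dataset <- local({
  env <- new.env()
  function(n = 24L, seed = 7L) {
    key <- paste0("ds", n, "_", seed)
    if (is.null(env[[key]])) {
      dir <- file.path(tempdir(), paste0("efds_", n, "_", seed))
      man <- generate_dataset(n, dir, seed = seed)
      env[[key]] <- man
    }
    env[[key]]
  }
})
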
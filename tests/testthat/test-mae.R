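test_that("encoder sees only visible tokens (information barrier)", {
  grid <- micro_grid()
  model <- init_mae(grid, micro_cfg(), seed = 3)
  cl <- random_clip(grid, seed = 1)
  mask <- make_mask(grid_L(grid), 0.5, seed = 2)

  tok <- cube_embed(cl, grid, model$params$embed)
  enc <- encode_visible(model, tok, mask)
  expect_identical(nrow(enc$reps), length(mask$visible))
  expect_identical(ncol(enc$reps), grid$d_model)

  # rho = 0 -> all tokens pass through
  m0 <- make_mask(grid_L(grid), 0)
  enc0 <- encode_visible(model, tok, m0)
  expect_identical(nrow(enc0$reps), grid_L(grid))

  # perturbing masked-cube pixel content leaves the output unchanged
  px2 <- cl$pixels
  co <- token_coords(grid)
  i <- mask$masked[1]
  tt <- co[i, "t"] * grid$tau + 1; hh <- co[i, "h"] * grid$h + 1
  ww <- co[i, "w"] * grid$w + 1
  px2[tt, , hh, ww] <- 1 - px2[tt, , hh, ww]
  tok2 <- cube_embed(video_clip(px2), grid, model$params$embed)
  enc2 <- encode_visible(model, tok2, mask)
  expect_equal(enc2$reps, enc$reps, tolerance = 1e-12)

  # mismatched mask -> contract error
  bad <- make_mask(grid_L(grid) + 8L, 0.5)
  expect_error(encode_visible(model, tok, bad), "contract error")
})

test_that("gradient flows to the embedding only through visible cubes", {
  grid <- micro_grid()
  model <- init_mae(grid, micro_cfg(), seed = 5)
  cl <- random_clip(grid, seed = 2)
  mask <- make_mask(grid_L(grid), 0.5, seed = 7)
  fw <- mae_forward(model, cl, mask)
  gr <- mae_backward(model, fw$cache)
  # the embedding-weight gradient is X_vis' dTok: contributions only from
  # visible rows, so zeroing visible cubes' pixels must zero the gradient
  cubes <- cube_gather(cl$pixels, grid)
  contrib <- cubes
  contrib[mask$masked, ] <- 0
  # finite-difference: perturb a masked cube's pixels; loss changes only
  # through the reconstruction target, not through the encoder
  px2 <- cl$pixels
  idx <- cube_pixel_index(grid)[mask$masked[1], 1]
  px2[idx] <- px2[idx] + 1e-4
  fw2 <- mae_forward(model, video_clip(clip01(px2)), mask)
  # target-side derivative of mean squared error
  d_num <- (fw2$loss - fw$loss) / 1e-4
  nM <- length(mask$masked)
  d_ana <- -2 * fw$cache$diff[1, 1] / (nM * ncol(cubes))
  expect_equal(d_num, d_ana, tolerance = 1e-2)
})

test_that("decoder reconstructs the full clip shape for any mask", {
  grid <- micro_grid()
  model <- init_mae(grid, micro_cfg(), seed = 1)
  cl <- random_clip(grid, seed = 3)
  tok <- cube_embed(cl, grid, model$params$embed)
  for (rho in c(0, 0.5, 0.9)) {
    mask <- make_mask(grid_L(grid), rho, seed = 4)
    enc <- encode_visible(model, tok, mask)
    dec <- decode_full(model, enc$reps, mask)
    expect_identical(dim(dec$pixels), dim(cl$pixels))
  }
  # zero decoder output weights -> reconstruction equals the output bias
  m2 <- model
  m2$params$to_pixels$W[] <- 0
  m2$params$to_pixels$b[] <- 0.25
  mask <- make_mask(grid_L(grid), 0.5, seed = 5)
  enc <- encode_visible(m2, tok, mask)
  dec <- decode_full(m2, enc$reps, mask)
  expect_equal(as.vector(dec$pixels), rep(0.25, length(dec$pixels)))
})

test_that("reconstruction loss is supported on masked cubes only", {
  grid <- micro_grid()
  cl <- random_clip(grid, seed = 6)
  mask <- make_mask(grid_L(grid), 0.5, seed = 8)
  expect_equal(reconstruction_loss(cl, cl$pixels, mask, grid), 0)
  # perturbing visible cubes leaves the loss unchanged
  Vh <- cl$pixels + 0.01
  base <- reconstruction_loss(cl, Vh, mask, grid)
  rows <- cube_gather(Vh, grid)
  rows[mask$visible, ] <- runif(length(mask$visible) * ncol(rows))
  expect_equal(reconstruction_loss(cl, cube_scatter(rows, grid), mask, grid),
               base, tolerance = 1e-12)
  # single masked cube, V = 0, V_hat = 1 -> loss 1
  zero <- array(0, dim = dim(cl$pixels))
  one <- array(1, dim = dim(cl$pixels))
  m1 <- make_mask(grid_L(grid), 0.2, seed = 1)    # floor(0.2 * 8) = 1 cube
  expect_identical(length(m1$masked), 1L)
  expect_equal(reconstruction_loss(zero, one, m1, grid), 1)
  expect_error(reconstruction_loss(cl, Vh, make_mask(grid_L(grid), 0), grid),
               "undefined-loss")
})

test_that("encoder cost scales with the number of visible tokens", {
  grid <- tiny_grid()
  model <- init_mae(grid, tiny_cfg(), seed = 2)
  cl <- random_clip(grid, seed = 4)
  tok <- cube_embed(cl, grid, model$params$embed)
  L <- grid_L(grid)
  for (rho in c(0.5, 0.85)) {
    mask <- make_mask(L, rho, seed = 3)
    enc <- encode_visible(model, tok, mask)
    # token-count accounting: every encoder activation has |visible| rows
    expect_identical(nrow(enc$reps), L - as.integer(floor(rho * L)))
    expect_identical(nrow(enc$cache$X_last), L - as.integer(floor(rho * L)))
  }
})

test_that("lr schedule hits its printed endpoints", {
  total <- 1000
  expect_equal(lr_schedule(0, total), 1e-5)
  expect_equal(lr_schedule(0.05 * total, total), 1e-4)
  expect_equal(lr_schedule(total, total), 0)
  expect_equal(lr_schedule(total, total, floor_lr = 1e-6), 1e-6)
  # monotone on the ramp, decreasing after the peak
  ramp <- sapply(seq(0, 50, by = 10), lr_schedule, total_steps = total)
  expect_true(all(diff(ramp) > 0))
  tail <- sapply(seq(50, 1000, by = 50), lr_schedule, total_steps = total)
  expect_true(all(diff(tail) < 0))
})

test_that("pre-training is deterministic and decreases loss on two ratios", {
  grid <- micro_grid()
  cfg <- micro_cfg()
  cl <- tiny_phantom_clip(seed = 3, T = 4L)
  st <- pretrain_state(epochs = 30, batch_size = 1, peak_lr = 1e-3,
                       mask_ratio = 0.85, seed = 11)
  ck1 <- run_pretraining(NULL, grid, cfg, st, clips = list(cl))
  ck2 <- run_pretraining(NULL, grid, cfg, st, clips = list(cl))
  expect_identical(ck1$history$loss, ck2$history$loss)
  # moving-average decrease for both high and medium mask ratios
  for (rho in c(0.85, 0.5)) {
    st2 <- pretrain_state(epochs = 40, batch_size = 1, peak_lr = 1e-3,
                          mask_ratio = rho, seed = 5)
    ck <- run_pretraining(NULL, grid, cfg, st2, clips = list(cl))
    ma <- stats::filter(ck$history$loss, rep(1 / 10, 10), sides = 1)
    ma <- ma[!is.na(ma)]
    expect_lt(ma[length(ma)], ma[1])
  }
  # checkpoints round-trip through disk
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck1, path)
  back <- load_checkpoint(path)
  expect_equal(back$model$params, ck1$model$params)
  expect_error(run_pretraining(NULL, grid, cfg, st, clips = list()),
               "data error")
})
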
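test_that("gated attention pooling: simplex weights, K=1 identity, permutation", {
  set.seed(5)
  d <- 16L
  gp <- init_gated_attention(d, L = 32, sd = 0.3)
  X <- matrix(rnorm(7 * d), 7, d)
  out <- gated_attention_pool(X, gp)
  expect_equal(sum(out$weights), 1)
  expect_true(all(out$weights > 0))
  # pooled vector lies in the convex hull: coordinate-wise between min/max
  expect_true(all(out$pooled >= apply(X, 2, min) - 1e-12))
  expect_true(all(out$pooled <= apply(X, 2, max) + 1e-12))
  # K = 1 -> identity
  one <- gated_attention_pool(X[3, , drop = FALSE], gp)
  expect_equal(one$weights, 1)
  expect_equal(one$pooled, as.vector(X[3, ]))
  # permutation invariance of the pooled vector
  perm <- sample(7)
  out_p <- gated_attention_pool(X[perm, , drop = FALSE], gp)
  expect_equal(out_p$pooled, out$pooled, tolerance = 1e-12)
  expect_equal(out_p$weights, out$weights[perm], tolerance = 1e-12)
})

test_that("gated attention matches a direct formula oracle", {
  set.seed(6)
  d <- 8L
  gp <- init_gated_attention(d, L = 12, sd = 0.5)
  X <- matrix(rnorm(5 * d), 5, d)
  # independent oracle: literal per-instance evaluation
  scores <- vapply(seq_len(5), function(k) {
    x <- X[k, ]
    sum(gp$w * (tanh(gp$V %*% x) * (1 / (1 + exp(-gp$U %*% x)))))
  }, numeric(1))
  wts <- exp(scores - max(scores)); wts <- wts / sum(wts)
  pooled <- colSums(X * wts)
  out <- gated_attention_pool(X, gp)
  expect_equal(out$weights, wts, tolerance = 1e-12)
  expect_equal(out$pooled, pooled, tolerance = 1e-12)
})

test_that("pathway output widths and fused concatenation", {
  grid <- tiny_grid()
  stf <- init_stf(grid, L_gate = 32, seed = 9)
  set.seed(1)
  L <- grid_L(grid)
  tok <- matrix(rnorm(L * grid$d_model), L)
  fi <- 0:(grid$T - 1)
  j <- joint_pathway(stf, tok)
  dj <- disjoint_pathway(stf, tok, fi)
  expect_identical(length(j$out), grid$d_model)
  expect_identical(length(dj$out), grid$d_model)
  expect_identical(length(j$weights), L)
  expect_identical(length(dj$weights), grid$t_bar)
  fr <- fuse(stf, tok, fi)
  expect_identical(length(fr$fused), 2L * grid$d_model)
  expect_equal(fr$fused, c(fr$joint_vec, fr$disjoint_vec))
  expect_equal(fr$joint_vec, j$out)
  # determinism
  fr2 <- fuse(stf, tok, fi)
  expect_identical(fr$fused, fr2$fused)
  # the paper-scale width contract: d_model 768 -> fused 1536 (no compute,
  # pure arithmetic on the concatenation contract)
  expect_identical(2L * 768L, 1536L)
})

test_that("zeroing one pathway's influence only changes its half of fused", {
  grid <- tiny_grid()
  stf <- init_stf(grid, L_gate = 16, seed = 4)
  set.seed(2)
  L <- grid_L(grid)
  tok <- matrix(rnorm(L * grid$d_model), L)
  fi <- 0:(grid$T - 1)
  base <- fuse(stf, tok, fi)
  stf2 <- stf
  stf2$params$gate_disjoint$w[] <- stf2$params$gate_disjoint$w + 0.3
  mod <- fuse(stf2, tok, fi)
  expect_equal(mod$fused[seq_len(grid$d_model)],
               base$fused[seq_len(grid$d_model)], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(mod$disjoint_vec, base$disjoint_vec)))
})

test_that("joint pathway is position-sensitive through its 3D encodings", {
  grid <- tiny_grid()
  set.seed(3)
  L <- grid_L(grid)
  tok <- matrix(rnorm(L * grid$d_model), L)
  perm <- sample(L)
  stf <- init_stf(grid, L_gate = 16, seed = 2)
  # with positional encodings disabled and the residual stack bypassed
  # (zero conv output weights), pooling is permutation invariant
  stf0 <- stf
  stf0$pos_enc3d[] <- 0
  for (s in 1:3) stf0$params$res3d[[s]]$conv$W[] <- 0
  for (s in 1:3) stf0$params$res3d[[s]]$gn$b[] <- 0
  a <- joint_pathway(stf0, tok)
  b <- joint_pathway(stf0, tok[perm, , drop = FALSE])
  expect_equal(a$out, b$out, tolerance = 1e-10)
  # with encodings enabled the output generally changes under permutation
  a1 <- joint_pathway(stf, tok)
  b1 <- joint_pathway(stf, tok[perm, , drop = FALSE])
  expect_false(isTRUE(all.equal(a1$out, b1$out)))
})

test_that("all-zero tokens with zero conv weights pool the positional field", {
  grid <- tiny_grid()
  stf <- init_stf(grid, L_gate = 16, seed = 8)
  for (s in 1:3) {
    stf$params$res3d[[s]]$conv$W[] <- 0
    stf$params$res3d[[s]]$conv$b[] <- 0
    stf$params$res3d[[s]]$gn$b[] <- 0
  }
  tok <- matrix(0, grid_L(grid), grid$d_model)
  j <- joint_pathway(stf, tok)
  # degenerate forward pass: res block reduces to identity on the encodings,
  # so the pooled vector is a gated-attention pool of the encodings alone
  oracle <- gated_attention_pool(stf$pos_enc3d, stf$params$gate_joint)
  expect_equal(j$out, oracle$pooled, tolerance = 1e-12)
})

test_that("sparse encodings average frame indices in groups of tau", {
  grid <- tiny_grid()           # tau = 2, T = 8 -> t_bar = 4
  E <- sinusoid_encoding(0:7, grid$d_model)
  avg <- group_average_encodings(E, 2L)
  expect_identical(dim(avg), c(4L, grid$d_model))
  expect_equal(avg[1, ], (E[1, ] + E[2, ]) / 2)
  expect_equal(avg[4, ], (E[7, ] + E[8, ]) / 2)
  # T = 16, tau = 2: pairs (0,1), (2,3), ..., (14,15) — hand enumeration
  E16 <- sinusoid_encoding(0:15, 12L)
  avg16 <- group_average_encodings(E16, 2L)
  for (g in 1:8) {
    expect_equal(avg16[g, ], colMeans(E16[c(2 * g - 1, 2 * g), ]))
  }
  # frame-index mismatch -> configuration error
  stf <- init_stf(grid, L_gate = 16, seed = 1)
  tok <- matrix(0, grid_L(grid), grid$d_model)
  expect_error(disjoint_pathway(stf, tok, 0:6), "configuration error")
})

test_that("t_bar = 1 disjoint pathway assigns pooling weight one", {
  grid <- cube_grid_spec(T = 2, H = 32, W = 32, tau = 2, h = 16, w = 16,
                         d_model = 12)
  stf <- init_stf(grid, L_gate = 8, seed = 3)
  set.seed(9)
  tok <- matrix(rnorm(grid_L(grid) * 12), grid_L(grid))
  dj <- disjoint_pathway(stf, tok, 0:1)
  expect_equal(dj$weights, 1)
  expect_identical(length(dj$out), 12L)
})
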
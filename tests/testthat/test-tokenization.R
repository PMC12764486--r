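test_that("seq_length matches the embedding-length formula", {
  expect_identical(seq_length(16, 2, 224, 16, 224, 16), 1568L)
  expect_identical(seq_length(4, 4, 16, 16, 16, 16), 1L)
  expect_error(seq_length(16, 3, 224, 16, 224, 16), "configuration error")
  expect_error(seq_length(16, 2, 224, 15, 224, 16), "configuration error")
})

test_that("raster bijection between sequence index and grid coordinates", {
  grid <- cube_grid_spec(T = 6, H = 48, W = 64, tau = 2, h = 16, w = 16,
                         d_model = 12)
  co <- token_coords(grid)
  # reshape-to-grid then flatten is the identity
  back <- token_index(grid, co[, "t"], co[, "h"], co[, "w"])
  expect_identical(back, seq_len(grid_L(grid)))
  # t-major ordering: first h_bar*w_bar tokens are slab t = 0
  expect_true(all(co[seq_len(grid$h_bar * grid$w_bar), "t"] == 0))
})

test_that("cube gather/scatter round-trips and cubes are local", {
  grid <- tiny_grid()
  cl <- random_clip(grid, seed = 9)
  rows <- cube_gather(cl$pixels, grid)
  expect_identical(dim(rows), c(grid_L(grid), grid$tau * grid$h * grid$w * 3L))
  expect_equal(cube_scatter(rows, grid), cl$pixels)
  # perturbing only cube 1's pixels changes only row 1
  px2 <- cl$pixels
  px2[1, , 1, 1] <- 1 - px2[1, , 1, 1]     # frame 0, top-left = cube (0,0,0)
  rows2 <- cube_gather(px2, grid)
  changed <- which(rowSums(rows2 != rows) > 0)
  expect_identical(changed, 1L)
})

test_that("cube embedding is a shared linear map in raster order", {
  grid <- tiny_grid(d_model = 16L)
  w <- init_cube_embed(grid, seed = 4)
  # zero clip, zero bias -> all-zero tokens
  z <- cube_embed(array(0, dim = c(grid$T, 3, grid$H, grid$W)), grid, w)
  expect_true(all(z$tokens == 0))
  expect_identical(dim(z$tokens), c(grid_L(grid), 16L))
  # constant clip -> all tokens equal
  cc <- cube_embed(array(0.5, dim = c(grid$T, 3, grid$H, grid$W)), grid, w)
  expect_lt(max(abs(sweep(cc$tokens, 2L, cc$tokens[1, ]))), 1e-12)
  # locality: clips differing inside one cube differ at exactly that token
  cl <- random_clip(grid, seed = 2)
  px2 <- cl$pixels
  px2[3, 2, 20, 20] <- 1 - px2[3, 2, 20, 20]  # cube (t=1, h=1, w=1) -> index
  i <- token_index(grid, 1, 1, 1)
  t1 <- cube_embed(cl$pixels, grid, w)$tokens
  t2 <- cube_embed(px2, grid, w)$tokens
  diffrow <- which(rowSums(abs(t1 - t2)) > 0)
  expect_identical(diffrow, as.integer(i))
})

test_that("make_mask sizes, partition, determinism, and errors", {
  for (rho in c(0.5, 0.7, 0.8, 0.85, 0.9)) {
    m <- make_mask(1568L, rho, seed = 13)
    expect_identical(length(m$masked), as.integer(floor(rho * 1568)))
    expect_identical(sort(c(m$masked, m$visible)), seq_len(1568L))
    expect_identical(length(intersect(m$masked, m$visible)), 0L)
  }
  expect_identical(length(make_mask(1568L, 0.85, 1)$masked), 1332L)
  expect_identical(length(make_mask(1568L, 0.85, 1)$visible), 236L)
  expect_identical(make_mask(64L, 0)$masked, integer(0))
  expect_identical(make_mask(512L, 0.7, seed = 5)$masked,
                   make_mask(512L, 0.7, seed = 5)$masked)
  expect_false(identical(make_mask(512L, 0.7, seed = 5)$masked,
                         make_mask(512L, 0.7, seed = 6)$masked))
  expect_error(make_mask(64L, 1.0), "parameter error")
  expect_error(make_mask(64L, -0.1), "parameter error")
})

test_that("mask inclusion is uniform across seeds (chi-square sanity)", {
  L <- 64L; rho <- 0.5; n_seeds <- 1000L
  counts <- integer(L)
  for (s in seq_len(n_seeds)) {
    counts[make_mask(L, rho, seed = s)$masked] <-
      counts[make_mask(L, rho, seed = s)$masked] + 1L
  }
  expected <- n_seeds * floor(rho * L) / L
  chisq <- sum((counts - expected)^2 / expected)
  # within one draw the inclusion indicators are negatively correlated (the
  # mask size is fixed), which deflates the statistic relative to the
  # independent chi-square reference; only the upper bound is meaningful and
  # it guards against a biased sampler
  expect_lt(chisq, qchisq(0.999, df = L - 1))
  # every token is maskable and none is always masked
  expect_true(all(counts > 0) && all(counts < n_seeds))
})

test_that("scatter/gather on visible indices restores visible entries", {
  grid <- tiny_grid()
  L <- grid_L(grid)
  tok <- matrix(rnorm(L * grid$d_model), L)
  m <- make_mask(L, 0.85, seed = 3)
  vis <- tok[m$visible, , drop = FALSE]
  full <- matrix(0, L, grid$d_model)
  full[m$visible, ] <- vis
  expect_identical(full[m$visible, ], tok[m$visible, ])
  expect_true(all(full[m$masked, ] == 0))
})

test_that("3D positional encodings are deterministic, bounded, injective", {
  grid <- cube_grid_spec(T = 4, H = 32, W = 32, tau = 2, h = 16, w = 16,
                         d_model = 12)
  E1 <- positional_encoding_3d(grid)
  E2 <- positional_encoding_3d(grid)
  expect_identical(E1, E2)
  expect_true(all(E1 >= -1 & E1 <= 1))
  # injective: all pairwise rows distinct on the 2x2x2 grid
  dists <- as.matrix(stats::dist(E1))
  diag(dists) <- Inf
  expect_gt(min(dists), 1e-6)
  # larger d_model with remainder channels still fine
  E3 <- positional_encoding_3d(tiny_grid(d_model = 64L))
  expect_identical(dim(E3), c(16L, 64L))
})
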
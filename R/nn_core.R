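## Minimal neural-network core: parameter trees, dense/transformer layers
## with hand-derived backward passes, and an AdamW optimizer. No external
## tensor library exists in this environment, so every gradient here is
## written out explicitly and verified by finite differences in the tests.

## Parameter trees -----------------------------------------------------------
## Parameters and gradients are nested named lists whose leaves are numeric
## vectors/matrices. Leaves with >= 2 dimensions count as "weights" for
## decoupled weight decay; vectors (biases, norm gains, mask tokens) do not.

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    # align by name where available so list construction order cannot drift
    if (!is.null(names(x)) && !is.null(names(y)) && all(names(x) %in% names(y))) {
      y <- y[names(x)]
    }
    mapply(function(a, b) tree_map2(f, a, b), x, y, SIMPLIFY = FALSE)
  } else {
    f(x, y)
  }
}

tree_zeros <- function(x) tree_map(function(a) a * 0, x)

tree_add <- function(x, y) tree_map2(`+`, x, y)

tree_scale <- function(x, s) tree_map(function(a) a * s, x)

# Sum of squared leaves (for grad-norm diagnostics).
tree_sumsq <- function(x) {
  if (is.list(x)) sum(vapply(x, tree_sumsq, numeric(1))) else sum(x^2)
}

## Primitive layers ----------------------------------------------------------

init_linear <- function(d_in, d_out, sd = 0.02) {
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out),
       b = numeric(d_out))
}

linear_fwd <- function(X, p) sweep(X %*% p$W, 2L, p$b, "+")

linear_bwd <- function(dY, X, p) {
  list(dX = dY %*% t(p$W),
       grads = list(W = t(X) %*% dY, b = colSums(dY)))
}

init_layernorm <- function(d) list(g = rep(1, d), b = numeric(d))

.ln_eps <- 1e-5

layernorm_fwd <- function(X, p) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  sd <- sqrt(v + .ln_eps)
  xhat <- xc / sd
  out <- sweep(sweep(xhat, 2L, p$g, "*"), 2L, p$b, "+")
  list(out = out, cache = list(xhat = xhat, sd = sd))
}

layernorm_bwd <- function(dY, p, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, p$g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) / cache$sd
  list(dX = dX,
       grads = list(g = colSums(dY * xhat), b = colSums(dY)))
}

gelu_fwd <- function(X) X * stats::pnorm(X)

gelu_bwd <- function(dY, X) dY * (stats::pnorm(X) + X * stats::dnorm(X))

relu_fwd <- function(X) pmax(X, 0)

relu_bwd <- function(dY, X) dY * (X > 0)

# Backward of row-wise softmax: given outputs A and upstream dA.
softmax_rows_bwd <- function(A, dA) A * (dA - rowSums(dA * A))

## Multi-head self-attention -------------------------------------------------

init_attention <- function(d, n_heads, sd = 0.02) {
  assert_that(d %% n_heads == 0L, "d_model must be divisible by n_heads")
  list(q = init_linear(d, d, sd), k = init_linear(d, d, sd),
       v = init_linear(d, d, sd), o = init_linear(d, d, sd))
}

attention_fwd <- function(X, p, n_heads) {
  d <- ncol(X); dh <- d %/% n_heads
  Q <- linear_fwd(X, p$q); K <- linear_fwd(X, p$k); V <- linear_fwd(X, p$v)
  O <- matrix(0, nrow(X), d)
  A_list <- vector("list", n_heads)
  for (hh in seq_len(n_heads)) {
    cols <- (hh - 1L) * dh + seq_len(dh)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
    A <- softmax_rows(S)
    A_list[[hh]] <- A
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  out <- linear_fwd(O, p$o)
  list(out = out,
       cache = list(X = X, Q = Q, K = K, V = V, O = O, A = A_list,
                    n_heads = n_heads))
}

attention_bwd <- function(dOut, p, cache) {
  X <- cache$X; n_heads <- cache$n_heads
  d <- ncol(X); dh <- d %/% n_heads
  ob <- linear_bwd(dOut, cache$O, p$o)
  dO <- ob$dX
  dQ <- matrix(0, nrow(X), d); dK <- dQ; dV <- dQ
  for (hh in seq_len(n_heads)) {
    cols <- (hh - 1L) * dh + seq_len(dh)
    A <- cache$A[[hh]]
    Vh <- cache$V[, cols, drop = FALSE]
    dOh <- dO[, cols, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, cols] <- t(A) %*% dOh
    dS <- softmax_rows_bwd(A, dA) / sqrt(dh)
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE]
    dK[, cols] <- t(dS) %*% cache$Q[, cols, drop = FALSE]
  }
  qb <- linear_bwd(dQ, X, p$q)
  kb <- linear_bwd(dK, X, p$k)
  vb <- linear_bwd(dV, X, p$v)
  list(dX = qb$dX + kb$dX + vb$dX,
       grads = list(q = qb$grads, k = kb$grads, v = vb$grads, o = ob$grads))
}

## Pre-norm transformer block and stack --------------------------------------

init_block <- function(d, n_heads, mlp_ratio = 4, sd = 0.02) {
  dh <- round(d * mlp_ratio)
  list(ln1 = init_layernorm(d), attn = init_attention(d, n_heads, sd),
       ln2 = init_layernorm(d),
       fc1 = init_linear(d, dh, sd), fc2 = init_linear(dh, d, sd))
}

block_fwd <- function(X, p, n_heads) {
  l1 <- layernorm_fwd(X, p$ln1)
  at <- attention_fwd(l1$out, p$attn, n_heads)
  h1 <- X + at$out
  l2 <- layernorm_fwd(h1, p$ln2)
  z1 <- linear_fwd(l2$out, p$fc1)
  a1 <- gelu_fwd(z1)
  out <- h1 + linear_fwd(a1, p$fc2)
  list(out = out,
       cache = list(l1 = l1, at = at, h1 = h1, l2 = l2, z1 = z1, a1 = a1))
}

block_bwd <- function(dOut, p, cache) {
  f2 <- linear_bwd(dOut, cache$a1, p$fc2)
  dz1 <- gelu_bwd(f2$dX, cache$z1)
  f1 <- linear_bwd(dz1, cache$l2$out, p$fc1)
  l2 <- layernorm_bwd(f1$dX, p$ln2, cache$l2$cache)
  dh1 <- dOut + l2$dX
  ab <- attention_bwd(dh1, p$attn, cache$at$cache)
  l1 <- layernorm_bwd(ab$dX, p$ln1, cache$l1$cache)
  list(dX = dh1 + l1$dX,
       grads = list(ln1 = l1$grads, attn = ab$grads, ln2 = l2$grads,
                    fc1 = f1$grads, fc2 = f2$grads))
}

init_transformer <- function(depth, d, n_heads, mlp_ratio = 4, sd = 0.02) {
  list(blocks = lapply(seq_len(depth), function(i) init_block(d, n_heads, mlp_ratio, sd)),
       ln_f = init_layernorm(d))
}

# Forward through a block stack + final layernorm. When `want_attention`,
# also returns each layer's head-averaged attention matrix (row-stochastic).
transformer_fwd <- function(X, p, n_heads, want_attention = FALSE) {
  caches <- vector("list", length(p$blocks))
  attn <- if (want_attention) vector("list", length(p$blocks)) else NULL
  for (i in seq_along(p$blocks)) {
    b <- block_fwd(X, p$blocks[[i]], n_heads)
    caches[[i]] <- b$cache
    if (want_attention) {
      attn[[i]] <- Reduce(`+`, b$cache$at$cache$A) / length(b$cache$at$cache$A)
    }
    X <- b$out
  }
  lf <- layernorm_fwd(X, p$ln_f)
  list(out = lf$out, cache = list(blocks = caches, ln_f = lf$cache, X_last = X),
       attention = attn)
}

transformer_bwd <- function(dOut, p, cache) {
  lf <- layernorm_bwd(dOut, p$ln_f, cache$ln_f)
  dX <- lf$dX
  gb <- vector("list", length(p$blocks))
  for (i in rev(seq_along(p$blocks))) {
    bb <- block_bwd(dX, p$blocks[[i]], cache$blocks[[i]])
    gb[[i]] <- bb$grads
    dX <- bb$dX
  }
  list(dX = dX, grads = list(blocks = gb, ln_f = lf$grads))
}

## Losses --------------------------------------------------------------------

# Softmax cross-entropy for one sample; logits numeric vector, y 1-based class.
ce_loss <- function(logits, y) {
  p <- softmax_vec(logits)
  d <- p
  d[y] <- d[y] - 1
  list(loss = -log(max(p[y], 1e-300)), dlogits = d, probs = p)
}

## AdamW ---------------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), step = 0L)
}

# One decoupled-weight-decay Adam step. Decay applies only to leaves with a
# dim attribute (weight matrices), never to vectors (biases, norm gains).
adam_step <- function(params, grads, state, lr, betas = c(0.9, 0.95),
                      eps = 1e-8, weight_decay = 0) {
  state$step <- state$step + 1L
  b1 <- betas[1]; b2 <- betas[2]
  state$m <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
  c1 <- 1 - b1^state$step
  c2 <- 1 - b2^state$step
  upd <- tree_map2(function(m, v) (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) {
    wd <- if (!is.null(dim(p))) weight_decay else 0
    p - lr * (u + wd * p)
  }, params, upd)
  list(params = params, state = state)
}
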
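test_that("task heads have the contracted shapes", {
  reg <- task_spec("regression", "ef")
  h <- attach_head(128L, reg, seed = 1)
  out <- head_forward(h, rnorm(128))
  expect_identical(length(out$out), 1L)
  # 5-class severity-style head -> 5 logits
  cls <- task_spec("classification", "as_grade", n_classes = 5L)
  h5 <- attach_head(64L, cls, seed = 2)
  expect_identical(length(head_forward(h5, rnorm(64))$out), 5L)
  # zero weights -> constant output equal to the final bias
  hz <- attach_head(16L, reg, seed = 3)
  hz$fc1$W[] <- 0; hz$fc1$b[] <- 0; hz$fc2$W[] <- 0; hz$fc2$b[] <- 0.7
  expect_equal(head_forward(hz, rnorm(16))$out, 0.7)
  # width mismatch -> contract error
  expect_error(head_forward(h, rnorm(64)), "contract error")
})

test_that("label transforms round-trip exactly", {
  vol <- task_spec("regression", "esv", log_scale = TRUE)
  expect_equal(transform_labels(1, vol), 0)
  expect_equal(inverse_transform_labels(0, vol), 1)
  set.seed(4)
  x <- exp(rnorm(50))
  expect_equal(inverse_transform_labels(transform_labels(x, vol), vol), x,
               tolerance = 1e-12)
  expect_error(transform_labels(c(1, -2), vol), "data error")
  # identity branch for EF
  ef <- task_spec("regression", "ef")
  expect_identical(transform_labels(x, ef), x)
})

test_that("EF threshold labels use >= at the boundary", {
  expect_identical(ef_threshold_labels(55, 0.5), 1L)
  expect_identical(ef_threshold_labels(45, 0.5), 0L)
  expect_identical(ef_threshold_labels(45, 0.45), 1L)
  expect_identical(ef_threshold_labels(50, 0.5), 1L)
  expect_identical(ef_threshold_labels(c(30, 50, 70), 0.5), c(0L, 1L, 1L))
})

test_that("regression metrics match hand computation and brute force", {
  expect_equal(regression_metrics(c(1, 2, 3), c(1, 2, 3)),
               list(mae = 0, mse = 0, rmse = 0, r2 = 1))
  truth <- c(1, 2, 3)
  m <- regression_metrics(rep(mean(truth), 3), truth)
  expect_equal(m$r2, 0)
  m2 <- regression_metrics(c(2, 2, 2), truth)
  expect_equal(m2$mae, 2 / 3)
  expect_equal(m2$r2, 0)
  # brute-force oracle on random vectors
  set.seed(8)
  for (rep in 1:5) {
    n <- sample(5:50, 1)
    p <- rnorm(n); t <- rnorm(n)
    m <- regression_metrics(p, t)
    expect_equal(m$mae, sum(abs(p - t)) / n)
    expect_equal(m$mse, sum((p - t)^2) / n)
    expect_equal(m$rmse, sqrt(m$mse))
    expect_equal(m$r2, 1 - sum((p - t)^2) / sum((t - mean(t))^2))
  }
  expect_error(regression_metrics(c(1, 2), c(5, 5)), "r2 undefined")
})

test_that("classification metrics match enumeration oracles", {
  # printed 4-point example: labels (0,0,1,1), scores (.1,.4,.35,.8) -> auc .75
  s <- cbind(1 - c(0.1, 0.4, 0.35, 0.8), c(0.1, 0.4, 0.35, 0.8))
  m <- classification_metrics(s, c(0L, 0L, 1L, 1L), 2L)
  expect_equal(m$auc, 0.75)
  # perfectly separated -> auc 1
  s2 <- cbind(c(0.9, 0.8, 0.2, 0.1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(classification_metrics(s2, c(0L, 0L, 1L, 1L), 2L)$auc, 1)
  # one-hot scores -> accuracy 1, f1 1
  oh <- diag(3)[c(1, 2, 3, 2), ]
  m3 <- classification_metrics(oh, c(0L, 1L, 2L, 1L), 3L)
  expect_equal(m3$accuracy, 1)
  expect_equal(m3$f1, 1)
  # brute-force pairwise AUC oracle on random binary problems
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(6:40, 1)
    lab <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    sc <- runif(n)
    pairs <- expand.grid(i = which(lab == 1L), j = which(lab == 0L))
    oracle <- mean(ifelse(sc[pairs$i] > sc[pairs$j], 1,
                          ifelse(sc[pairs$i] == sc[pairs$j], 0.5, 0)))
    m <- classification_metrics(cbind(1 - sc, sc), lab, 2L)
    expect_equal(m$auc, oracle, tolerance = 1e-12)
  }
  expect_error(classification_metrics(s2, c(1L, 1L, 1L, 1L), 2L), "AUC undefined")
})

test_that("clinical metrics behave under shift, sign, and oracle", {
  t <- c(40, 55, 62, 35, 50)
  m <- clinical_metrics(t, t)
  expect_equal(m$cor, 100)
  expect_equal(m$bias, 0)
  expect_equal(m$std, 0)
  m2 <- clinical_metrics(t + 5, t)
  expect_equal(m2$cor, 100)
  expect_equal(m2$bias, 5)
  expect_equal(m2$std, 0)
  expect_equal(clinical_metrics(-t, t)$cor, -100)
  # brute-force oracle
  set.seed(10)
  p <- rnorm(30, 50, 10); q <- rnorm(30, 50, 10)
  m3 <- clinical_metrics(p, q)
  expect_equal(m3$cor, 100 * sum((p - mean(p)) * (q - mean(q))) /
                 sqrt(sum((p - mean(p))^2) * sum((q - mean(q))^2)))
  expect_equal(m3$bias, mean(p) - mean(q))
  expect_equal(m3$std, sqrt(sum((p - q - mean(p - q))^2) / 29))
  expect_error(clinical_metrics(rep(1, 5), t), "cor undefined")
})

test_that("bootstrap CI contains the point estimate and shrinks with n", {
  set.seed(11)
  widths <- vapply(c(50, 200, 800), function(n) {
    t <- rnorm(n, 50, 10)
    p <- t + rnorm(n, 0, 3)
    ci <- bootstrap_ci(p, t, regression_metrics, n_boot = 300, seed = 1)
    expect_true(ci$point$mae >= ci$ci95[1, "mae"] &&
                  ci$point$mae <= ci$ci95[2, "mae"])
    ci$ci95[2, "mae"] - ci$ci95[1, "mae"]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("linear probe freezes the encoder and solves separable problems", {
  grid <- micro_grid()
  model <- init_mae(grid, micro_cfg(), seed = 6)
  dir <- withr::local_tempdir()
  man <- generate_dataset(16, dir, split_fractions = c(0.5, 0.25),
                          base_params = phantom_params(T_raw = 8, H = 32, W = 32),
                          seed = 21)
  before <- model$params$encoder
  task <- task_spec("regression", "ef")
  # adapt the loader to T = 4 frames of the micro grid
  data <- list(train = load_labeled_split(man, grid, "ef", "train"),
               val = load_labeled_split(man, grid, "ef", "val"))
  fit <- linear_probe(model, man, task, opts = list(epochs = 3, seed = 1),
                      data = data)
  expect_identical(fit$encoder_model$params$encoder, before)
  # probing on linearly separable features reaches accuracy 1
  set.seed(3)
  n <- 60
  X <- cbind(matrix(rnorm(n * 3), n, 3), rep(c(-2, 2), each = n / 2))
  y <- rep(0:1, each = n / 2)
  probe <- init_linear(4L, 2L)
  st <- adam_init(probe)
  ctask <- task_spec("classification", "lbl", n_classes = 2L)
  for (it in 1:300) {
    grads <- NULL
    for (i in seq_len(n)) {
      out <- as.vector(linear_fwd(X[i, , drop = FALSE], probe))
      tl <- task_loss(ctask, out, y[i])
      lb <- linear_bwd(matrix(tl$dout, 1L), X[i, , drop = FALSE], probe)
      grads <- if (is.null(grads)) lb$grads else tree_add(grads, lb$grads)
    }
    o <- adam_step(probe, tree_scale(grads, 1 / n), st, lr = 0.05)
    probe <- o$params; st <- o$state
  }
  scores <- t(apply(X %*% probe$W + rep(probe$b, each = n), 1, softmax_vec))
  expect_equal(classification_metrics(scores, y, 2L)$accuracy, 1)
})

test_that("fine-tuning selects the argmin-validation epoch deterministically", {
  grid <- micro_grid()
  dir <- withr::local_tempdir()
  man <- generate_dataset(12, dir, split_fractions = c(0.5, 0.25),
                          base_params = phantom_params(T_raw = 8, H = 32, W = 32),
                          seed = 31)
  task <- task_spec("regression", "ef")
  data <- list(train = load_labeled_split(man, grid, "ef", "train"),
               val = load_labeled_split(man, grid, "ef", "val"))
  opts <- list(epochs = 4, batch_size = 4, peak_lr = 1e-3, use_stf = FALSE,
               seed = 2)
  fit <- finetune(NULL, man, task, grid = grid, cfg = micro_cfg(),
                  opts = opts, data = data)
  expect_identical(fit$best_epoch, which.min(fit$history$val_loss))
  expect_lte(min(fit$history$val_loss), fit$history$val_loss[fit$best_epoch])
  fit2 <- finetune(NULL, man, task, grid = grid, cfg = micro_cfg(),
                   opts = opts, data = data)
  expect_identical(fit2$best_epoch, fit$best_epoch)
  expect_equal(predict_model(fit, data$val$clips),
               predict_model(fit2, data$val$clips))
})

test_that("volumes train in log space but are scored on the raw scale", {
  task <- task_spec("regression", "esv", log_scale = TRUE)
  y <- c(30, 45, 60, 80)
  st <- target_stats(task, y)
  z <- unlist(prepare_targets(task, y, st))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  # round trip through the stored stats reproduces the raw volumes
  raw <- inverse_transform_labels(z * st$sd + st$mu, task)
  expect_equal(raw, y, tolerance = 1e-9)
})
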
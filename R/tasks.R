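## Downstream task heads, fine-tuning / linear-probing loops, label
## transforms, and regression / classification / clinical metrics.

#' Downstream task specification
#'
#' @param kind `"regression"` or `"classification"`.
#' @param target label name in the manifest (`ef` %, `esv`/`edv` ml, or a
#'   class label).
#' @param log_scale train volumes in natural-log space (predictions are
#'   always rescaled back to raw units before scoring). Only valid for
#'   strictly positive targets.
#' @param ef_threshold EF fraction (0.50 or 0.45) used to derive binary
#'   heart-function labels; positive class = EF at or above threshold
#'   (preserved function).
#' @param n_classes number of classes for classification.
#' @return object of class `task_spec`.
#' @export
task_spec <- function(kind = c("regression", "classification"),
                      target = "ef", log_scale = FALSE,
                      ef_threshold = 0.5, n_classes = 2L) {
  kind <- match.arg(kind)
  assert_that(ef_threshold > 0 && ef_threshold < 1,
              "ef_threshold must lie in (0, 1)")
  structure(list(kind = kind, target = target, log_scale = log_scale,
                 ef_threshold = ef_threshold, n_classes = as.integer(n_classes)),
            class = "task_spec")
}

#' Transform labels for training; inverse to recover raw scale
#'
#' Volumes are trained in natural-log space for stability; the identity is
#' used otherwise. `inverse_transform_labels()` is the exact inverse.
#'
#' @param values numeric labels.
#' @param task a [task_spec()].
#' @return transformed values.
#' @export
transform_labels <- function(values, task) {
  if (isTRUE(task$log_scale)) {
    assert_that(all(values > 0),
                "data error: non-positive label under log scaling")
    log(values)
  } else values
}

#' @rdname transform_labels
#' @export
inverse_transform_labels <- function(values, task) {
  if (isTRUE(task$log_scale)) exp(values) else values
}

#' Binary heart-function labels from EF values
#'
#' Label 1 (positive, preserved function) iff `ef / 100 >= threshold`.
#'
#' @param ef_values EF in percent, each in (0, 100).
#' @param threshold EF fraction, e.g. 0.5 or 0.45.
#' @return integer vector of 0/1 labels.
#' @export
ef_threshold_labels <- function(ef_values, threshold = 0.5) {
  as.integer(ef_values / 100 >= threshold)
}

## Task heads -----------------------------------------------------------------

#' Attach an MLP task head
#'
#' Two linear layers with a ReLU between, emitting one output for
#' regression or `n_classes` logits for classification.
#'
#' @param fused_width input width (`d_model` for mean pooling,
#'   `2 * d_model` with STF-Net).
#' @param task a [task_spec()].
#' @param hidden hidden width (default `fused_width`).
#' @param seed integer seed.
#' @return head parameter list of class `task_head`.
#' @export
attach_head <- function(fused_width, task, hidden = NULL, seed = 1L) {
  assert_that(is_count(fused_width), "fused_width must be a positive integer")
  if (is.null(hidden)) hidden <- fused_width
  n_out <- if (task$kind == "regression") 1L else task$n_classes
  p <- with_seed(seed, list(fc1 = init_linear(fused_width, hidden),
                            fc2 = init_linear(hidden, n_out)))
  structure(p, class = "task_head", width = fused_width)
}

head_forward <- function(head, rep) {
  x <- matrix(rep, 1L)
  assert_that(ncol(x) == attr(head, "width"),
              "contract error: representation width does not match head")
  z1 <- linear_fwd(x, head$fc1)
  a1 <- relu_fwd(z1)
  out <- linear_fwd(a1, head$fc2)
  list(out = as.vector(out), cache = list(x = x, z1 = z1, a1 = a1))
}

head_backward <- function(head, dout, cache) {
  f2 <- linear_bwd(matrix(dout, 1L), cache$a1, head$fc2)
  dz1 <- relu_bwd(f2$dX, cache$z1)
  f1 <- linear_bwd(dz1, cache$x, head$fc1)
  list(drep = as.vector(f1$dX), grads = list(fc1 = f1$grads, fc2 = f2$grads))
}

## Metrics --------------------------------------------------------------------

#' Regression metrics: MAE, MSE, RMSE, coefficient of determination
#'
#' Computed on raw-scale values (call [inverse_transform_labels()] first if
#' the model was trained in log space).
#'
#' @param pred,truth numeric vectors of equal length >= 2.
#' @return named list `mae`, `mse`, `rmse`, `r2`.
#' @export
regression_metrics <- function(pred, truth) {
  assert_that(length(pred) == length(truth) && length(pred) >= 2L,
              "pred and truth must have equal length >= 2")
  if (stats::var(truth) == 0) stop2("r2 undefined: truth values are all equal")
  err <- pred - truth
  mse <- mean(err^2)
  list(mae = mean(abs(err)), mse = mse, rmse = sqrt(mse),
       r2 = 1 - sum(err^2) / sum((truth - mean(truth))^2))
}

# Binary AUC by the rank-sum (Mann-Whitney) statistic, ties averaged.
.auc_binary <- function(scores, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop2("AUC undefined: only one class present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.f1_binary <- function(pred_pos, true_pos) {
  tp <- sum(pred_pos & true_pos)
  fp <- sum(pred_pos & !true_pos)
  fn <- sum(!pred_pos & true_pos)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Classification metrics: accuracy, AUC, F1
#'
#' Binary tasks use the positive-class score for AUC and the positive-class
#' F1; multi-class tasks use macro one-vs-rest AUC and macro F1. Accuracy is
#' by argmax.
#'
#' @param scores matrix `n x n_classes` of class probabilities (rows sum to 1).
#' @param labels integer labels in `0 .. n_classes - 1` (positive class = 1
#'   for binary tasks).
#' @param n_classes number of classes.
#' @return named list `accuracy`, `auc`, `f1`.
#' @export
classification_metrics <- function(scores, labels, n_classes = ncol(scores)) {
  scores <- as.matrix(scores)
  assert_that(ncol(scores) == n_classes, "scores must have n_classes columns")
  assert_that(all(labels %in% 0:(n_classes - 1L)),
              "labels must lie in 0 .. n_classes - 1")
  assert_that(max(abs(rowSums(scores) - 1)) < 1e-6,
              "score rows must sum to 1")
  pred <- max.col(scores, ties.method = "first") - 1L
  acc <- mean(pred == labels)
  if (n_classes == 2L) {
    auc <- .auc_binary(scores[, 2L], labels == 1L)
    f1 <- .f1_binary(pred == 1L, labels == 1L)
  } else {
    present <- sort(unique(labels))
    if (length(present) < 2L) stop2("AUC undefined: only one class present")
    aucs <- vapply(present, function(k) .auc_binary(scores[, k + 1L], labels == k),
                   numeric(1))
    auc <- mean(aucs)
    f1 <- mean(vapply(0:(n_classes - 1L),
                      function(k) .f1_binary(pred == k, labels == k), numeric(1)))
  }
  list(accuracy = acc, auc = auc, f1 = f1)
}

#' Clinical agreement metrics for EF estimation
#'
#' Pearson correlation in percent, mean bias, and the standard deviation of
#' the prediction errors.
#'
#' @param pred_ef,truth_ef numeric vectors of equal length >= 2.
#' @return named list `cor` (%), `bias`, `std`.
#' @export
clinical_metrics <- function(pred_ef, truth_ef) {
  assert_that(length(pred_ef) == length(truth_ef) && length(pred_ef) >= 2L,
              "need equal-length vectors of length >= 2")
  if (stats::var(pred_ef) == 0 || stats::var(truth_ef) == 0) {
    stop2("cor undefined: zero variance")
  }
  d <- pred_ef - truth_ef
  list(cor = 100 * stats::cor(pred_ef, truth_ef),
       bias = mean(d), std = stats::sd(d))
}

#' Bootstrap 95% confidence intervals for a metric set
#'
#' Nonparametric bootstrap over test clips (1000 replicates by default);
#' percentile intervals.
#'
#' @param pred,truth aligned prediction / truth vectors.
#' @param metric_fn function `(pred, truth) -> named list` of scalar metrics.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return list with `point` (named list) and `ci95` (2-row matrix, one
#'   column per metric).
#' @export
bootstrap_ci <- function(pred, truth, metric_fn = regression_metrics,
                         n_boot = 1000L, seed = 1L) {
  point <- metric_fn(pred, truth)
  n <- length(pred)
  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        val <- tryCatch(unlist(metric_fn(pred[idx], truth[idx])),
                        error = function(e) NULL)
        if (!is.null(val)) return(val)
      }
    }, numeric(length(point)))
  })
  ci <- apply(draws, 1L, stats::quantile, probs = c(0.025, 0.975))
  list(point = point, ci95 = ci)
}

## Downstream data loading ----------------------------------------------------

# Load clips and aligned labels for one split.
load_labeled_split <- function(manifest, grid, target, split) {
  sub <- manifest[manifest$label_name == target & manifest$split == split, ,
                  drop = FALSE]
  if (nrow(sub) == 0L) stop2(sprintf("data error: no '%s' labels in '%s' split",
                                     target, split))
  sub <- sub[order(sub$path), , drop = FALSE]
  clips <- lapply(sub$path, function(p) {
    raw <- read_video(p)
    clip <- uniform_temporal_sample(raw, grid$T, source_id = p)
    d <- dim(clip$pixels)
    if (d[3] != grid$H || d[4] != grid$W) clip <- resize_and_normalize(clip, grid$H, grid$W)
    clip
  })
  list(clips = clips, y = as.numeric(sub$label_value), paths = sub$path)
}

## Downstream forward / backward ----------------------------------------------

# Forward one clip through encoder (+ STF or mean pooling) + head.
downstream_forward <- function(fit, clip) {
  model <- fit$encoder_model
  cubes <- cube_gather(if (inherits(clip, "video_clip")) clip$pixels else clip,
                       model$grid)
  tok <- sweep(cubes %*% model$params$embed$W, 2L, model$params$embed$b, "+")
  X <- tok + model$pos_enc
  enc <- transformer_fwd(X, model$params$encoder, model$cfg$heads)
  if (!is.null(fit$stf)) {
    sf <- stf_forward(fit$stf, enc$out, clip$frame_indices)
    rep <- sf$fused
  } else {
    sf <- NULL
    rep <- colMeans(enc$out)
  }
  hd <- head_forward(fit$head, rep)
  list(out = hd$out,
       cache = list(cubes = cubes, enc = enc, sf = sf, hd = hd$cache))
}

# Backward from d(out); returns grads for (embed, encoder, stf, head).
downstream_backward <- function(fit, dout, cache, freeze_encoder = FALSE) {
  model <- fit$encoder_model
  hb <- head_backward(fit$head, dout, cache$hd)
  if (!is.null(fit$stf)) {
    sb <- stf_backward(fit$stf, hb$drep, cache$sf$cache)
    dreps <- sb$dtokens
    stf_grads <- sb$grads
  } else {
    L <- nrow(cache$enc$out)
    dreps <- matrix(hb$drep / L, L, length(hb$drep), byrow = TRUE)
    stf_grads <- NULL
  }
  if (freeze_encoder) {
    return(list(head = hb$grads, stf = stf_grads, embed = NULL, encoder = NULL))
  }
  eb <- transformer_bwd(dreps, model$params$encoder, cache$enc$cache)
  list(head = hb$grads, stf = stf_grads,
       embed = list(W = t(cache$cubes) %*% eb$dX, b = colSums(eb$dX)),
       encoder = eb$grads)
}

# Per-sample loss and output gradient on the transformed scale.
task_loss <- function(task, out, y_t) {
  if (task$kind == "regression") {
    diff <- out - y_t
    list(loss = diff^2, dout = 2 * diff)
  } else {
    ce <- ce_loss(out, y_t + 1L)            # labels 0-based -> 1-based class
    list(loss = ce$loss, dout = ce$dlogits)
  }
}

## Fine-tuning ----------------------------------------------------------------

#' Fine-tune a pre-trained encoder on a downstream task
#'
#' End-to-end gradient updates of encoder (+ optional STF-Net) + MLP head
#' with AdamW (betas 0.9/0.98, weight decay 1e-3) under cosine learning-rate
#' decay. The epoch with the lowest validation loss is kept.
#'
#' @param checkpoint an `mae_checkpoint` from [run_pretraining()], an
#'   `mae_model`, or `NULL` for a randomly initialized encoder.
#' @param manifest manifest data frame with train/val/test splits.
#' @param task a [task_spec()].
#' @param grid,cfg required when `checkpoint` is `NULL`.
#' @param opts list of options: `epochs` (50), `batch_size` (16), `peak_lr`
#'   (1e-3), `weight_decay` (1e-3), `betas` (0.9, 0.98), `use_stf` (TRUE),
#'   `L_gate`, `head_hidden`, `seed`.
#' @param data optional pre-loaded splits (list with `train`, `val` entries
#'   as returned by the internal loader) to bypass disk.
#' @return object of class `finetuned_model`.
#' @export
finetune <- function(checkpoint, manifest, task, grid = NULL, cfg = NULL,
                     opts = list(), data = NULL) {
  o <- utils::modifyList(list(epochs = 50L, batch_size = 16L, peak_lr = 1e-3,
                              weight_decay = 1e-3, betas = c(0.9, 0.98),
                              use_stf = TRUE, L_gate = 1024L,
                              head_hidden = NULL, seed = 1L),
                         opts)
  model <- resolve_encoder(checkpoint, grid, cfg, seed = derive_seed(o$seed, "enc"))
  grid <- model$grid
  d <- grid$d_model

  stf <- if (isTRUE(o$use_stf)) {
    init_stf(grid, L_gate = o$L_gate, seed = derive_seed(o$seed, "stf"))
  } else NULL
  width <- if (is.null(stf)) d else 2L * d
  head <- attach_head(width, task, hidden = o$head_hidden,
                      seed = derive_seed(o$seed, "head"))
  fit <- structure(list(encoder_model = model, stf = stf, head = head,
                        task = task, use_stf = isTRUE(o$use_stf)),
                   class = "finetuned_model")

  if (is.null(data)) {
    data <- list(train = load_labeled_split(manifest, grid, task$target, "train"),
                 val = load_labeled_split(manifest, grid, task$target, "val"))
  }
  tstats <- target_stats(task, data$train$y)
  y_tr <- prepare_targets(task, data$train$y, tstats)
  y_va <- prepare_targets(task, data$val$y, tstats)
  fit$target_stats <- tstats
  n <- length(data$train$clips)

  params <- list(embed = model$params$embed, encoder = model$params$encoder,
                 head = unclass(head))
  if (!is.null(stf)) params$stf <- stf$params
  opt <- adam_init(params)
  steps_per_epoch <- ceiling(n / o$batch_size)
  total_steps <- o$epochs * steps_per_epoch

  set_params <- function(fit, params) {
    fit$encoder_model$params$embed <- params$embed
    fit$encoder_model$params$encoder <- params$encoder
    head <- fit$head
    head$fc1 <- params$head$fc1; head$fc2 <- params$head$fc2
    fit$head <- head
    if (!is.null(fit$stf)) fit$stf$params <- params$stf
    fit
  }

  best <- list(val = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  step <- 0L
  with_seed(derive_seed(o$seed, "ft"), {
    for (ep in seq_len(o$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (b in seq_len(steps_per_epoch)) {
        ids <- ord[((b - 1L) * o$batch_size + 1L):min(b * o$batch_size, n)]
        grads <- NULL
        for (id in ids) {
          fw <- downstream_forward(fit, data$train$clips[[id]])
          tl <- task_loss(task, fw$out, y_tr[[id]])
          ep_loss <- ep_loss + tl$loss
          bw <- downstream_backward(fit, tl$dout, fw$cache)
          g <- list(embed = bw$embed, encoder = bw$encoder, head = bw$head)
          if (!is.null(stf)) g$stf <- bw$stf
          grads <- if (is.null(grads)) g else tree_add(grads, g)
        }
        grads <- tree_scale(grads, 1 / length(ids))
        step <- step + 1L
        lr <- o$peak_lr * 0.5 * (1 + cos(pi * step / total_steps))
        upd <- adam_step(params, grads, opt, lr, o$betas,
                         weight_decay = o$weight_decay)
        params <- upd$params
        opt <- upd$state
        fit <- set_params(fit, params)
      }
      vl <- mean(vapply(seq_along(data$val$clips), function(i) {
        fw <- downstream_forward(fit, data$val$clips[[i]])
        task_loss(task, fw$out, y_va[[i]])$loss
      }, numeric(1)))
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / n,
                                     val_loss = vl))
      if (vl < best$val) best <- list(val = vl, params = params, epoch = ep)
    }
  })
  fit <- set_params(fit, best$params)
  fit$best_epoch <- best$epoch
  fit$history <- hist
  fit
}

# Accept a checkpoint, a model, or NULL (random init).
resolve_encoder <- function(checkpoint, grid, cfg, seed = 1L) {
  if (is.null(checkpoint)) {
    assert_that(!is.null(grid) && !is.null(cfg),
                "grid and cfg are required for a random-init encoder")
    init_mae(grid, cfg, seed = seed)
  } else if (inherits(checkpoint, "mae_checkpoint")) {
    checkpoint$model
  } else if (inherits(checkpoint, "mae_model")) {
    checkpoint
  } else stop2("checkpoint must be an mae_checkpoint, mae_model, or NULL")
}

# Targets on the training scale: transformed values (regression) or 0-based
# integer class labels (classification, derived from EF threshold when the
# target is EF).
prepare_targets <- function(task, y, stats = NULL) {
  if (task$kind == "regression") {
    yt <- transform_labels(y, task)
    if (!is.null(stats)) yt <- (yt - stats$mu) / stats$sd
    as.list(yt)
  } else {
    as.list(if (task$target == "ef") ef_threshold_labels(y, task$ef_threshold)
            else as.integer(y))
  }
}

# Train-split standardization of regression targets (after any log
# transform). At toy step counts an optimizer cannot reach raw-percent
# targets from a zero-init head, so training happens in z-score space and
# predictions are mapped back before scoring.
target_stats <- function(task, y_train) {
  if (task$kind != "regression") return(NULL)
  yt <- transform_labels(y_train, task)
  s <- stats::sd(yt)
  list(mu = mean(yt), sd = if (is.finite(s) && s > 0) s else 1)
}

#' Predict with a fitted downstream model
#'
#' @param fit a `finetuned_model` or `linear_probe_model`.
#' @param clips list of [video_clip()]s.
#' @return regression: numeric predictions on the raw scale;
#'   classification: matrix of class probabilities.
#' @export
predict_model <- function(fit, clips) {
  fwd <- if (inherits(fit, "linear_probe_model")) {
    function(cl) probe_forward(fit, cl)
  } else if (inherits(fit, "stf_probe_model")) {
    function(cl) stf_probe_forward(fit, cl)
  } else {
    function(cl) downstream_forward(fit, cl)$out
  }
  outs <- lapply(clips, fwd)
  if (fit$task$kind == "regression") {
    z <- vapply(outs, `[[`, numeric(1), 1L)
    st <- fit$target_stats
    if (!is.null(st)) z <- z * st$sd + st$mu
    inverse_transform_labels(z, fit$task)
  } else {
    do.call(rbind, lapply(outs, softmax_vec))
  }
}

#' Evaluate a fitted model on a manifest split
#'
#' @param fit a fitted model.
#' @param manifest manifest data frame.
#' @param split split tag (default `"test"`).
#' @param data optional pre-loaded split.
#' @param n_boot bootstrap replicates for 95% CIs (0 disables).
#' @param seed integer seed for the bootstrap.
#' @return a `metrics_report` list: `metrics`, optional `clinical`, `ci95`,
#'   `n`, plus raw `pred`/`truth`.
#' @export
evaluate_model <- function(fit, manifest, split = "test", data = NULL,
                           n_boot = 0L, seed = 1L) {
  grid <- fit$encoder_model$grid
  if (is.null(data)) {
    data <- load_labeled_split(manifest, grid, fit$task$target, split)
  }
  pred <- predict_model(fit, data$clips)
  task <- fit$task
  if (task$kind == "regression") {
    truth <- data$y
    metrics <- regression_metrics(pred, truth)
    clinical <- if (task$target == "ef") clinical_metrics(pred, truth) else NULL
    ci <- if (n_boot > 0) bootstrap_ci(pred, truth, regression_metrics,
                                       n_boot = n_boot, seed = seed)$ci95 else NULL
  } else {
    truth <- unlist(prepare_targets(task, data$y))
    metrics <- classification_metrics(pred, truth, task$n_classes)
    clinical <- NULL
    ci <- if (n_boot > 0) {
      bootstrap_ci(seq_along(truth), truth,
                   function(idx, tr) classification_metrics(
                     pred[idx, , drop = FALSE], tr, task$n_classes),
                   n_boot = n_boot, seed = seed)$ci95
    } else NULL
  }
  structure(list(metrics = metrics, clinical = clinical, ci95 = ci,
                 n = length(truth), pred = pred, truth = truth),
            class = "metrics_report")
}

## Linear probing -------------------------------------------------------------

#' Linear probe on a frozen encoder
#'
#' The encoder is frozen (its weights are never touched); a single linear
#' map is trained by gradient descent on mean-pooled encoder
#' representations.
#'
#' @inheritParams finetune
#' @return object of class `linear_probe_model` (also usable with
#'   [predict_model()] / [evaluate_model()]).
#' @export
linear_probe <- function(checkpoint, manifest, task, opts = list(), data = NULL) {
  o <- utils::modifyList(list(epochs = 50L, batch_size = 16L, peak_lr = 1e-2,
                              weight_decay = 0, betas = c(0.9, 0.98),
                              seed = 1L), opts)
  model <- resolve_encoder(checkpoint, NULL, NULL)
  grid <- model$grid
  d <- grid$d_model
  if (is.null(data)) {
    data <- list(train = load_labeled_split(manifest, grid, task$target, "train"),
                 val = load_labeled_split(manifest, grid, task$target, "val"))
  }
  # frozen encoder: representations are computed once. Mean-pooled encoder
  # features have tiny across-clip variance (the final layer norm fixes the
  # per-token scale), so they are z-scored on the train split before the
  # probe -- the standard frozen-feature standardization in probing
  # protocols. The stats travel with the fitted probe.
  feats <- function(clips) {
    do.call(rbind, lapply(clips, function(cl) colMeans(encode_clip(model, cl)$reps)))
  }
  X_tr <- feats(data$train$clips)
  fstats <- list(mu = colMeans(X_tr),
                 sd = pmax(apply(X_tr, 2, stats::sd), 1e-8))
  std <- function(X) sweep(sweep(X, 2, fstats$mu), 2, fstats$sd, "/")
  X_tr <- std(X_tr)
  X_va <- std(feats(data$val$clips))
  tstats <- target_stats(task, data$train$y)
  y_tr <- prepare_targets(task, data$train$y, tstats)
  y_va <- prepare_targets(task, data$val$y, tstats)
  n_out <- if (task$kind == "regression") 1L else task$n_classes
  probe <- with_seed(derive_seed(o$seed, "probe"), init_linear(d, n_out))
  opt <- adam_init(probe)
  n <- nrow(X_tr)
  steps_per_epoch <- ceiling(n / o$batch_size)
  total_steps <- o$epochs * steps_per_epoch
  best <- list(val = Inf, probe = probe, epoch = 0L)
  step <- 0L
  with_seed(derive_seed(o$seed, "lp"), {
    for (ep in seq_len(o$epochs)) {
      ord <- sample.int(n)
      for (b in seq_len(steps_per_epoch)) {
        ids <- ord[((b - 1L) * o$batch_size + 1L):min(b * o$batch_size, n)]
        grads <- NULL
        for (id in ids) {
          x <- X_tr[id, , drop = FALSE]
          out <- as.vector(linear_fwd(x, probe))
          tl <- task_loss(task, out, y_tr[[id]])
          lb <- linear_bwd(matrix(tl$dout, 1L), x, probe)
          grads <- if (is.null(grads)) lb$grads else tree_add(grads, lb$grads)
        }
        grads <- tree_scale(grads, 1 / length(ids))
        step <- step + 1L
        lr <- o$peak_lr * 0.5 * (1 + cos(pi * step / total_steps))
        upd <- adam_step(probe, grads, opt, lr, o$betas,
                         weight_decay = o$weight_decay)
        probe <- upd$params
        opt <- upd$state
      }
      vl <- mean(vapply(seq_len(nrow(X_va)), function(i) {
        task_loss(task, as.vector(linear_fwd(X_va[i, , drop = FALSE], probe)),
                  y_va[[i]])$loss
      }, numeric(1)))
      if (vl < best$val) best <- list(val = vl, probe = probe, epoch = ep)
    }
  })
  structure(list(encoder_model = model, probe = best$probe, task = task,
                 best_epoch = best$epoch, target_stats = tstats,
                 feat_stats = fstats),
            class = "linear_probe_model")
}

# predict_model and evaluate_model detect probes by class:
probe_forward <- function(fit, clip) {
  rep <- colMeans(encode_clip(fit$encoder_model, clip)$reps)
  if (!is.null(fit$feat_stats)) {
    rep <- (rep - fit$feat_stats$mu) / fit$feat_stats$sd
  }
  as.vector(linear_fwd(matrix(rep, 1L), fit$probe))
}

#' STF-Net probe on a frozen encoder
#'
#' Counterpart of [linear_probe()] for the fusion network: the encoder is
#' frozen and its full-sequence representations are cached once; an
#' STF-Net plus a single linear map on the fused `2 * d_model` vector are
#' trained by gradient descent. Comparing this against [linear_probe()]
#' (mean pooling + linear map on the same frozen encoder) isolates the
#' contribution of the fusion network.
#'
#' @inheritParams finetune
#' @param opts options: `epochs`, `batch_size`, `peak_lr`, `weight_decay`,
#'   `betas`, `L_gate`, `seed`.
#' @return object of class `stf_probe_model`, usable with
#'   [predict_model()] / [evaluate_model()].
#' @export
stf_probe <- function(checkpoint, manifest, task, opts = list(), data = NULL) {
  o <- utils::modifyList(list(epochs = 50L, batch_size = 16L, peak_lr = 3e-3,
                              weight_decay = 0, betas = c(0.9, 0.98),
                              L_gate = 1024L, seed = 1L), opts)
  model <- resolve_encoder(checkpoint, NULL, NULL)
  grid <- model$grid
  d <- grid$d_model
  if (is.null(data)) {
    data <- list(train = load_labeled_split(manifest, grid, task$target, "train"),
                 val = load_labeled_split(manifest, grid, task$target, "val"))
  }
  cache_split <- function(split) {
    lapply(split$clips, function(cl) {
      list(reps = encode_clip(model, cl)$reps, fi = cl$frame_indices)
    })
  }
  R_tr <- cache_split(data$train)
  R_va <- cache_split(data$val)
  # z-score token features per channel over all train tokens: frozen-feature
  # standardization so across-clip signal is on unit scale for the STF head
  all_tr <- do.call(rbind, lapply(R_tr, `[[`, "reps"))
  fstats <- list(mu = colMeans(all_tr),
                 sd = pmax(apply(all_tr, 2, stats::sd), 1e-8))
  std_reps <- function(R) sweep(sweep(R, 2, fstats$mu), 2, fstats$sd, "/")
  R_tr <- lapply(R_tr, function(r) { r$reps <- std_reps(r$reps); r })
  R_va <- lapply(R_va, function(r) { r$reps <- std_reps(r$reps); r })
  tstats <- target_stats(task, data$train$y)
  y_tr <- prepare_targets(task, data$train$y, tstats)
  y_va <- prepare_targets(task, data$val$y, tstats)
  n_out <- if (task$kind == "regression") 1L else task$n_classes

  stf <- init_stf(grid, L_gate = o$L_gate, seed = derive_seed(o$seed, "stf"))
  params <- list(stf = stf$params,
                 probe = with_seed(derive_seed(o$seed, "head"),
                                   init_linear(2L * d, n_out)))
  opt <- adam_init(params)
  n <- length(R_tr)
  steps_per_epoch <- ceiling(n / o$batch_size)
  total_steps <- o$epochs * steps_per_epoch

  fwd1 <- function(params, rc) {
    s <- stf; s$params <- params$stf
    sf <- stf_forward(s, rc$reps, rc$fi)
    out <- as.vector(linear_fwd(matrix(sf$fused, 1L), params$probe))
    list(out = out, sf = sf, fused = sf$fused)
  }
  best <- list(val = Inf, params = params, epoch = 0L)
  step <- 0L
  with_seed(derive_seed(o$seed, "train"), {
    for (ep in seq_len(o$epochs)) {
      ord <- sample.int(n)
      for (b in seq_len(steps_per_epoch)) {
        ids <- ord[((b - 1L) * o$batch_size + 1L):min(b * o$batch_size, n)]
        grads <- NULL
        for (id in ids) {
          fw <- fwd1(params, R_tr[[id]])
          tl <- task_loss(task, fw$out, y_tr[[id]])
          lb <- linear_bwd(matrix(tl$dout, 1L), matrix(fw$fused, 1L), params$probe)
          s <- stf; s$params <- params$stf
          sb <- stf_backward(s, as.vector(lb$dX), fw$sf$cache)
          g <- list(stf = sb$grads, probe = lb$grads)
          grads <- if (is.null(grads)) g else tree_add(grads, g)
        }
        grads <- tree_scale(grads, 1 / length(ids))
        step <- step + 1L
        lr <- o$peak_lr * 0.5 * (1 + cos(pi * step / total_steps))
        upd <- adam_step(params, grads, opt, lr, o$betas,
                         weight_decay = o$weight_decay)
        params <- upd$params
        opt <- upd$state
      }
      vl <- mean(vapply(seq_along(R_va), function(i) {
        task_loss(task, fwd1(params, R_va[[i]])$out, y_va[[i]])$loss
      }, numeric(1)))
      if (vl < best$val) best <- list(val = vl, params = params, epoch = ep)
    }
  })
  stf$params <- best$params$stf
  structure(list(encoder_model = model, stf = stf, probe = best$params$probe,
                 task = task, best_epoch = best$epoch, target_stats = tstats,
                 feat_stats = fstats),
            class = "stf_probe_model")
}

stf_probe_forward <- function(fit, clip) {
  reps <- encode_clip(fit$encoder_model, clip)$reps
  if (!is.null(fit$feat_stats)) {
    reps <- sweep(sweep(reps, 2, fit$feat_stats$mu), 2, fit$feat_stats$sd, "/")
  }
  sf <- stf_forward(fit$stf, reps, clip$frame_indices)
  as.vector(linear_fwd(matrix(sf$fused, 1L), fit$probe))
}
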
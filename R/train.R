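# Training: cross-entropy losses, Adam, and the fit loops for CAST and WT.

#' Cross-entropy between predicted probabilities and a one-hot target
#'
#' `-sum(y * log(p))` with probabilities clamped at 1e-12.  Used with K = 10
#' classes for patch-level training and T = 8 types for slide-level training.
#'
#' @param probs length-K probability vector (sums to 1).
#' @param onehot length-K 0/1 target vector.
#' @return non-negative loss.
#' @examples
#' cross_entropy(rep(1 / 10, 10), c(1, rep(0, 9)))  # log(10)
#' @export
cross_entropy <- function(probs, onehot) {
  if (length(probs) != length(onehot))
    stop("probs and onehot must have equal length")
  if (abs(sum(probs) - 1) > 1e-6) stop("probs must sum to 1")
  -sum(onehot * log(pmax(probs, 1e-12)))
}

#' Training configuration
#'
#' Optimiser defaults follow the full-scale training recipe: Adam with
#' momenta 0.9/0.999, 160 epochs, learning rate 2e-3 at batch 64 for CAST and
#' 1e-3 at batch 8 for WT; the learning-rate schedule is constant unless
#' `lr_schedule = "cosine"`.  Desk-scale experiments override `epochs` and
#' batch sizes.
#'
#' @param cast_lr,cast_batch CAST learning rate and batch size.
#' @param wt_lr,wt_batch WT learning rate and batch size.
#' @param epochs training epochs.
#' @param beta1,beta2,eps Adam moments and stabiliser.
#' @param lr_schedule `"constant"` or `"cosine"`.
#' @param seed training seed (shuffling order).
#' @param val_frac fraction of the training items held out for validation
#'   when no explicit validation set is supplied.
#' @param early_stop_acc optional validation accuracy at which training stops
#'   early (NULL = run all epochs).
#' @param verbose print per-epoch progress.
#' @return list of class `"train_config"`.
#' @export
train_config <- function(cast_lr = 2e-3, cast_batch = 64L, wt_lr = 1e-3,
                         wt_batch = 8L, epochs = 160L, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8,
                         lr_schedule = c("constant", "cosine"), seed = 0L,
                         val_frac = 0.2, early_stop_acc = NULL,
                         verbose = FALSE) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(cast_lr >= 0, wt_lr >= 0, epochs >= 1L)
  structure(list(cast_lr = cast_lr, cast_batch = as.integer(cast_batch),
                 wt_lr = wt_lr, wt_batch = as.integer(wt_batch),
                 epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
                 eps = eps, lr_schedule = lr_schedule, seed = as.integer(seed),
                 val_frac = val_frac, early_stop_acc = early_stop_acc,
                 verbose = verbose),
            class = "train_config")
}

# ---- Adam ------------------------------------------------------------------

adam_new <- function(params, lr, beta1, beta2, eps) {
  st <- lapply(params, function(p) {
    list(m = array(0, dim(p$value)), v = array(0, dim(p$value)))
  })
  list(params = params, state = st, lr = lr, beta1 = beta1, beta2 = beta2,
       eps = eps, t = 0L)
}

adam_step <- function(opt, lr = NULL) {
  if (is.null(lr)) lr <- opt$lr
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    s <- opt$state[[i]]
    s$m <- b1 * s$m + (1 - b1) * g
    s$v <- b2 * s$v + (1 - b2) * g * g
    opt$state[[i]] <- s
    p$value <- p$value - lr * (s$m / c1) / (sqrt(s$v / c2) + opt$eps)
  }
  opt
}

sched_lr <- function(base, epoch, epochs, schedule) {
  if (schedule == "cosine") base * 0.5 * (1 + cos(pi * (epoch - 1) / epochs))
  else base
}

param_values <- function(params) lapply(params, function(p) p$value)
restore_values <- function(params, values) {
  for (i in seq_along(params)) params[[i]]$value <- values[[i]]
  invisible(NULL)
}

# generic seeded minibatch loop over items; forward_fn(idx) must return a
# loss node built on the current parameters and an accuracy
train_loop <- function(plist, n_items, batch, lr_base, cfg, forward_fn,
                       eval_fn, label) {
  opt <- adam_new(plist, lr_base, cfg$beta1, cfg$beta2, cfg$eps)
  log <- data.frame(epoch = integer(0L), train_loss = numeric(0L),
                    train_acc = numeric(0L), val_loss = numeric(0L),
                    val_acc = numeric(0L))
  best <- list(acc = -Inf, values = NULL)
  t0 <- proc.time()[["elapsed"]]
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n_items)
    lr <- sched_lr(lr_base, epoch, cfg$epochs, cfg$lr_schedule)
    tl <- 0; ta <- 0; nb <- 0L
    for (start in seq.int(1L, n_items, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n_items)]
      ag_zero_grads(plist)
      fw <- forward_fn(idx)
      ag_backward(fw$loss)
      opt <- adam_step(opt, lr)
      tl <- tl + fw$loss$value[1L, 1L] * length(idx)
      ta <- ta + fw$correct
      nb <- nb + length(idx)
    }
    ev <- eval_fn()
    log <- rbind(log, data.frame(epoch = epoch, train_loss = tl / nb,
                                 train_acc = ta / nb, val_loss = ev$loss,
                                 val_acc = ev$acc))
    if (!is.na(ev$acc) && ev$acc >= best$acc) {
      best$acc <- ev$acc
      best$values <- param_values(plist)
    }
    if (cfg$verbose)
      message(sprintf("[%s] epoch %d loss %.4f acc %.3f val %.3f", label,
                      epoch, tl / nb, ta / nb, ev$acc))
    if (!is.null(cfg$early_stop_acc) && !is.na(ev$acc) &&
        ev$acc >= cfg$early_stop_acc) break
  }
  if (!is.null(best$values)) restore_values(plist, best$values)
  attr(log, "wall_time") <- proc.time()[["elapsed"]] - t0
  log
}

# ---- CAST training ---------------------------------------------------------

#' Train a CAST patch classifier
#'
#' @param x training data: a `thw_dataset` (its "train" split is used and the
#'   "test" split becomes the validation set), or a list with `triplets` and
#'   `labels` (0-based).
#' @param cast_cfg a [cast_config()]; defaults to the desk-scale
#'   configuration.
#' @param train_cfg a [train_config()].
#' @param model optionally a pre-built [cast_model()] to continue training.
#' @param model_seed initialisation seed when `model` is NULL.
#' @param val optional explicit validation list (`triplets`, `labels`).
#' @return the fitted `"mcvit_cast"` object; `$log` holds the per-epoch
#'   train/validation loss and accuracy series (best-validation weights are
#'   retained).
#' @export
fit_cast <- function(x, cast_cfg = cast_config_tiny(), train_cfg = train_config(),
                     model = NULL, model_seed = 0L, val = NULL) {
  if (inherits(x, "thw_dataset")) {
    tr <- thw_patches(x, "train")
    if (is.null(val)) {
      te <- thw_patches(x, "test")
      if (length(te$triplets)) val <- te
    }
    x <- tr
  }
  n <- length(x$triplets)
  if (n == 0L) stop("empty training split")
  stopifnot(length(x$labels) == n)
  if (is.null(model)) model <- cast_model(cast_cfg, seed = model_seed)
  cfg <- model$config
  if (is.null(val)) {
    hold <- with_seed(train_cfg$seed + 1L,
                      sample.int(n, max(1L, round(train_cfg$val_frac * n))))
    val <- list(triplets = x$triplets[hold], labels = x$labels[hold])
    x <- list(triplets = x$triplets[-hold], labels = x$labels[-hold])
    n <- length(x$triplets)
  }
  plist <- collect_params(model$params)
  eval_fn <- function() {
    ev <- cast_eval(model, val$triplets, val$labels, train_cfg$cast_batch)
    list(loss = ev$loss, acc = ev$acc)
  }
  log <- with_seed(train_cfg$seed, {
    train_loop(plist, n, train_cfg$cast_batch, train_cfg$cast_lr, train_cfg,
               forward_fn = function(idx) {
                 nd <- cast_forward_node(model$params, cfg, x$triplets[idx])
                 loss <- ag_softmax_xent(nd$logits, x$labels[idx] + 1L)
                 pred <- apply(nd$logits$value, 1L, which.max) - 1L
                 list(loss = loss, correct = sum(pred == x$labels[idx]))
               },
               eval_fn = eval_fn, label = "cast")
  })
  model$log <- log
  model$train_cfg <- train_cfg
  model
}

cast_eval <- function(model, triplets, labels, batch = 64L) {
  n <- length(triplets)
  if (n == 0L) return(list(loss = NA_real_, acc = NA_real_, pred = integer(0L)))
  preds <- integer(n); loss <- 0
  probs <- matrix(NA_real_, n, model$config$n_classes)
  for (start in seq.int(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    fw <- cast_forward(model, triplets[idx])
    preds[idx] <- fw$predicted
    probs[idx, ] <- fw$probs
    loss <- loss - sum(log(pmax(fw$probs[cbind(seq_along(idx), labels[idx] + 1L)],
                                1e-12)))
  }
  list(loss = loss / n, acc = mean(preds == labels), pred = preds, probs = probs)
}

# ---- WT training -----------------------------------------------------------

#' Train a WT slide classifier
#'
#' @param mats list of slide feature matrices (`m x width`).
#' @param types 0-based thymoma type labels, one per matrix.
#' @param wt_cfg a [wt_config()].
#' @param train_cfg a [train_config()].
#' @param model optional pre-built [wt_model()].
#' @param model_seed initialisation seed when `model` is NULL.
#' @param val optional list(mats, types) validation set.
#' @param standardize standardise feature-matrix columns to zero mean / unit
#'   variance using training-set statistics (default).  CAST embeddings and
#'   the label scalar live on very different scales; without this the input
#'   projection starts near rank-1 and optimisation stalls.  The statistics
#'   are stored on the model and re-applied by [wt_forward()]/`predict()`.
#' @return fitted `"mcvit_wt"` object with `$log`.
#' @export
fit_wt <- function(mats, types, wt_cfg = wt_config_tiny(),
                   train_cfg = train_config(), model = NULL, model_seed = 0L,
                   val = NULL, standardize = TRUE) {
  n <- length(mats)
  if (n == 0L) stop("empty training split")
  stopifnot(length(types) == n)
  if (is.null(model)) model <- wt_model(wt_cfg, seed = model_seed)
  cfg <- model$config
  if (standardize) {
    all_rows <- do.call(rbind, lapply(mats, function(M) wt_expand(cfg, M)))
    model$scaling <- list(mu = colMeans(all_rows),
                          sd = pmax(apply(all_rows, 2L, stats::sd), 1e-8))
  }
  if (is.null(val)) {
    hold <- with_seed(train_cfg$seed + 1L,
                      sample.int(n, max(1L, round(train_cfg$val_frac * n))))
    val <- list(mats = mats[hold], types = types[hold])
    mats <- mats[-hold]; types <- types[-hold]
    n <- length(mats)
  }
  train_mats <- lapply(mats, function(M) wt_scale(model, wt_expand(cfg, M)))
  plist <- collect_params(model$params)
  eval_fn <- function() {
    ev <- wt_eval(model, val$mats, val$types, train_cfg$wt_batch)
    list(loss = ev$loss, acc = ev$acc)
  }
  log <- with_seed(train_cfg$seed, {
    train_loop(plist, n, train_cfg$wt_batch, train_cfg$wt_lr, train_cfg,
               forward_fn = function(idx) {
                 nd <- wt_forward_node(model$params, cfg, train_mats[idx],
                                       training = TRUE)
                 loss <- ag_softmax_xent(nd, types[idx] + 1L)
                 pred <- apply(nd$value, 1L, which.max) - 1L
                 list(loss = loss, correct = sum(pred == types[idx]))
               },
               eval_fn = eval_fn, label = "wt")
  })
  model$log <- log
  model$train_cfg <- train_cfg
  model
}

wt_eval <- function(model, mats, types, batch = 8L) {
  n <- length(mats)
  if (n == 0L) return(list(loss = NA_real_, acc = NA_real_, pred = integer(0L)))
  preds <- integer(n); loss <- 0
  probs <- matrix(NA_real_, n, model$config$n_types)
  for (start in seq.int(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    fw <- wt_forward(model, mats[idx])
    preds[idx] <- fw$predicted
    probs[idx, ] <- fw$probs
    loss <- loss - sum(log(pmax(fw$probs[cbind(seq_along(idx), types[idx] + 1L)],
                                1e-12)))
  }
  list(loss = loss / n, acc = mean(preds == types), pred = preds, probs = probs)
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Serialises the configuration and the parameter tree (in collection order)
#' with a version stamp; loading reconstructs the model and restores values,
#' so a save/load round trip reproduces forward passes exactly.
#'
#' @param model an `"mcvit_cast"` or `"mcvit_wt"` object.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  values <- param_values(collect_params(model$params))
  saveRDS(list(version = model$version, class = class(model)[1L],
               config = model$config, seed = model$seed, values = values,
               log = model$log, scaling = model$scaling),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return the restored model.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$version, "mcvit-checkpoint-1"))
    stop("unsupported checkpoint version: ", ck$version)
  model <- if (ck$class == "mcvit_cast") cast_model(ck$config, seed = ck$seed)
           else wt_model(ck$config, seed = ck$seed)
  restore_values(collect_params(model$params), ck$values)
  model$log <- ck$log
  model$scaling <- ck$scaling
  model
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.mcvit_cast <- function(x, ...) {
  cfg <- x$config
  cat("CAST patch classifier (", paste(cfg$stage_dims, collapse = "/"),
      " dims, grids ", paste(cfg$grid_sides, collapse = "/"), ")\n", sep = "")
  cat("branches:", paste(branch_names(cfg), collapse = " "),
      if (cfg$use_cam) "+ CAM" else "(no CAM)", "\n")
  cat("classes:", cfg$n_classes, " embedding:", cfg$embed_dim_out, "\n")
  if (!is.null(x$log))
    cat(sprintf("trained %d epochs; best val acc %.3f\n", nrow(x$log),
                max(x$log$val_acc, na.rm = TRUE)))
  else cat("untrained\n")
  invisible(x)
}

#' @export
print.mcvit_wt <- function(x, ...) {
  cfg <- x$config
  cat("WT slide classifier (width ", cfg$width, " -> dim ", cfg$model_dim,
      ", ", cfg$stages, "x", cfg$blocks_per_stage, " blocks, ",
      cfg$n_heads, " heads)\n", sep = "")
  if (!is.null(x$log))
    cat(sprintf("trained %d epochs; best val acc %.3f\n", nrow(x$log),
                max(x$log$val_acc, na.rm = TRUE)))
  else cat("untrained\n")
  invisible(x)
}

#' @export
summary.mcvit_cast <- function(object, ...) {
  print(object)
  np <- sum(vapply(collect_params(object$params),
                   function(p) length(p$value), numeric(1L)))
  cat("parameters:", format(np, big.mark = ","), "\n")
  if (!is.null(object$log)) print(utils::tail(object$log, 3L))
  invisible(object)
}

#' @export
summary.mcvit_wt <- summary.mcvit_cast

#' @export
predict.mcvit_cast <- function(object, newdata,
                               type = c("class", "prob", "embedding"), ...) {
  type <- match.arg(type)
  fw <- cast_forward(object, newdata)
  switch(type, class = fw$predicted, prob = fw$probs,
         embedding = fw$embedding)
}

#' @export
predict.mcvit_wt <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  fw <- wt_forward(object, newdata)
  switch(type, class = fw$predicted, prob = fw$probs)
}

#' @export
plot.mcvit_cast <- function(x, ...) {
  if (is.null(x$log)) stop("model has no training log")
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(x$log$epoch, x$log$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "training loss", ...)
  graphics::lines(x$log$epoch, x$log$val_loss, lty = 2)
  graphics::plot(x$log$epoch, x$log$train_acc, type = "l", xlab = "epoch",
                 ylab = "accuracy", ylim = c(0, 1), main = "accuracy", ...)
  graphics::lines(x$log$epoch, x$log$val_acc, lty = 2)
  invisible(x)
}

#' @export
plot.mcvit_wt <- plot.mcvit_cast
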
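# Training kit: cross-entropy loss, AdamW, cosine learning-rate schedule
# with linear warmup, the training/evaluation loops and classification
# metrics (micro accuracy and per-class precision/recall).

#' Cross-entropy loss
#'
#' Mean over the batch of `-log p_true`. By contract `pred` holds per-sample
#' probability vectors on the simplex; with `from_logits = TRUE` rows are
#' passed through a softmax first. Probabilities are clamped below at 1e-12,
#' so a zero probability on the true class yields a large finite loss
#' (about 27.6) rather than infinity.
#'
#' @param pred N x C matrix of class probabilities (or logits).
#' @param labels Integer class labels in 1..C.
#' @param from_logits Interpret `pred` as unnormalized logits.
#' @return Scalar loss.
#' @export
cross_entropy <- function(pred, labels, from_logits = FALSE) {
  if (from_logits) pred <- softmax_rows(pred)
  p <- pred[cbind(seq_len(nrow(pred)), labels)]
  mean(-log(pmax(p, 1e-12)))
}

#' Training configuration
#'
#' Defaults follow the published training protocol: AdamW with learning
#' rate 1e-4, eps 1e-8, betas (0.9, 0.999), weight decay 1e-4, batch size
#' 32, cosine schedule decaying to 1e-6 with warmup starting at 1e-6.
#'
#' @param lr Peak learning rate.
#' @param lr_min Final learning rate of the cosine schedule.
#' @param warmup_lr_init Learning rate at the first warmup step.
#' @param warmup_epochs Linear warmup length in epochs.
#' @param betas,eps,weight_decay AdamW moments, epsilon and decoupled weight
#'   decay.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs; also the schedule horizon.
#' @param steps Optional cap on the number of optimizer steps actually run.
#'   The cosine schedule still spans the full `epochs` horizon, so a short
#'   run sits on the early (near-peak) part of the schedule exactly as the
#'   same steps would during a full-length run.
#' @param seed Seed for data order and augmentation streams.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, lr_min = 1e-6, warmup_lr_init = 1e-6,
                         warmup_epochs = 20L, betas = c(0.9, 0.999),
                         eps = 1e-8, weight_decay = 1e-4, batch_size = 32L,
                         epochs = 500L, steps = NULL, seed = 0L) {
  stopifnot(lr_min <= lr, batch_size >= 1)
  structure(list(lr = lr, lr_min = lr_min, warmup_lr_init = warmup_lr_init,
                 warmup_epochs = as.integer(warmup_epochs), betas = betas,
                 eps = eps, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 steps = if (!is.null(steps)) as.integer(steps),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine learning-rate schedule with linear warmup
#'
#' Linear warmup from `warmup_lr_init` to `lr` over `warmup_steps`, then
#' cosine decay from `lr` to `lr_min` over the remaining steps.
#'
#' @param step 1-based step index.
#' @param total_steps Total optimizer steps.
#' @param warmup_steps Warmup steps.
#' @param lr,lr_min,warmup_lr_init Schedule anchors.
#' @return Learning rate at `step`.
#' @export
cosine_lr <- function(step, total_steps, warmup_steps = 0L, lr = 1e-4,
                      lr_min = 1e-6, warmup_lr_init = 1e-6) {
  if (warmup_steps > 0 && step <= warmup_steps) {
    return(warmup_lr_init + (lr - warmup_lr_init) * (step - 1) / warmup_steps)
  }
  prog <- (step - warmup_steps - 1) / max(1, total_steps - warmup_steps - 1)
  lr_min + 0.5 * (lr - lr_min) * (1 + cos(pi * prog))
}

adamw_init <- function(refs) {
  list(m = lapply(refs, function(r) r$env[[r$field]] * 0),
       v = lapply(refs, function(r) r$env[[r$field]] * 0), t = 0L)
}

adamw_step <- function(refs, grads, state, lr, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$betas[1]; b2 <- cfg$betas[2]
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (nm in names(refs)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    r <- refs[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + cfg$eps)
    w <- r$env[[r$field]]
    r$env[[r$field]] <- w - lr * (upd + cfg$weight_decay * w)
  }
  state
}

#' Train a model
#'
#' Mini-batch AdamW training with the cosine warmup schedule. Aborts with a
#' diagnostic if the loss diverges to NaN. Deterministic given
#' `train_cfg$seed` (data order and initialization derive from it).
#'
#' @param model A model from [build_model()] (modified in place).
#' @param x Image batch array (H, W, 3, N), already normalized.
#' @param y Integer labels in 1..C.
#' @param train_cfg A [train_config()].
#' @param log_file Optional path; per-step records are appended as JSON
#'   lines.
#' @param verbose Print progress every 50 steps.
#' @param eval_every Evaluate accuracy over the full training set (in
#'   evaluation mode) every this many steps; 0 disables periodic
#'   evaluation.
#' @param target_accuracy Optional full-set training accuracy at which to
#'   stop early (checked at the `eval_every` cadence).
#' @return List with the trained `model`, a data frame `log` (step, lr,
#'   loss, per-batch accuracy), `final_train_accuracy` (full training set
#'   after the last step) and `best_train_accuracy` (maximum of the
#'   periodic full-set evaluations and the final one).
#' @export
train <- function(model, x, y, train_cfg = train_config(), log_file = NULL,
                  verbose = FALSE, eval_every = 0L, target_accuracy = NULL) {
  N <- dim(x)[4]
  stopifnot(length(y) == N, N >= 1)
  cfg <- train_cfg
  steps_per_epoch <- max(1L, N %/% cfg$batch_size)
  horizon <- cfg$epochs * steps_per_epoch           # schedule horizon
  total_steps <- if (!is.null(cfg$steps)) cfg$steps else horizon
  horizon <- max(horizon, total_steps)
  warmup_steps <- cfg$warmup_epochs * steps_per_epoch
  if (warmup_steps >= horizon) warmup_steps <- 0L
  refs <- nn_collect(model)
  state <- adamw_init(refs)
  set.seed(cfg$seed + 1L)
  order_pool <- c()
  best_acc <- 0
  log <- vector("list", total_steps)
  for (step in seq_len(total_steps)) {
    if (length(order_pool) < cfg$batch_size) order_pool <- c(order_pool, sample.int(N))
    idx <- order_pool[seq_len(min(cfg$batch_size, N))]
    order_pool <- order_pool[-seq_len(min(cfg$batch_size, N))]
    xb <- x[, , , idx, drop = FALSE]
    yb <- y[idx]
    fwd <- model_forward(model, xb, training = TRUE)
    p <- softmax_rows(fwd$logits)
    loss <- cross_entropy(p, yb)
    if (!is.finite(loss)) {
      stop("training diverged at step ", step, " (loss = ", loss,
           "); try a lower learning rate")
    }
    acc <- mean(max.col(p, ties.method = "first") == yb)
    onehot <- matrix(0, length(yb), ncol(p))
    onehot[cbind(seq_along(yb), yb)] <- 1
    dlogits <- (p - onehot) / length(yb)
    grads <- model_backward(model, fwd, dlogits)
    lr <- cosine_lr(step, horizon, warmup_steps, cfg$lr, cfg$lr_min,
                    cfg$warmup_lr_init)
    state <- adamw_step(refs, grads, state, lr, cfg)
    rec <- list(step = step, lr = lr, loss = loss, accuracy = acc)
    stop_early <- FALSE
    if (eval_every > 0L && step %% eval_every == 0L) {
      full_acc <- mean(model_predict(model, x, type = "class") == y)
      best_acc <- max(best_acc, full_acc)
      rec$train_set_accuracy <- full_acc
      if (!is.null(target_accuracy) && full_acc >= target_accuracy)
        stop_early <- TRUE
    }
    log[[step]] <- rec
    if (!is.null(log_file))
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
          file = log_file, append = TRUE, sep = "")
    if (verbose && step %% 50L == 0L)
      message(sprintf("step %d/%d lr %.2e loss %.4f acc %.3f",
                      step, total_steps, lr, loss, acc))
    if (stop_early) {
      log <- log[seq_len(step)]
      break
    }
  }
  log <- do.call(rbind, lapply(log, function(r) {
    r$train_set_accuracy <- r$train_set_accuracy %||% NA_real_
    as.data.frame(r)
  }))
  fin <- mean(model_predict(model, x, type = "class") == y)
  list(model = model, log = log, final_train_accuracy = fin,
       best_train_accuracy = max(best_acc, fin))
}

# ---- metrics -------------------------------------------------------------

#' Confusion matrix
#'
#' @param true,pred Integer labels in 1..C.
#' @param num_classes Number of classes C.
#' @return C x C integer matrix; rows are true classes, columns predicted.
#' @export
confusion_matrix <- function(true, pred, num_classes) {
  cm <- matrix(0L, num_classes, num_classes)
  for (i in seq_along(true)) cm[true[i], pred[i]] <- cm[true[i], pred[i]] + 1L
  cm
}

#' Micro-averaged accuracy from a confusion matrix
#'
#' The standard micro accuracy is the diagonal over the total count; under
#' micro-averaging it coincides with micro recall and micro F1. The literal
#' ratio `sum(TP) / sum(TP + FP + FN)`, whose denominator counts every
#' off-diagonal error twice, is available with `literal = TRUE`.
#'
#' @param confusion Square non-negative count matrix.
#' @param literal Use the double-counting denominator form.
#' @return Scalar in (0, 1].
#' @export
micro_accuracy <- function(confusion, literal = FALSE) {
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  tp <- sum(diag(confusion))
  if (!literal) return(tp / sum(confusion))
  fp <- sum(colSums(confusion) - diag(confusion))
  fn <- sum(rowSums(confusion) - diag(confusion))
  tp / (tp + fp + fn)
}

#' Per-class precision/recall report
#'
#' `precision_i = TP_i / (TP_i + FP_i)`, `recall_i = TP_i / (TP_i + FN_i)`;
#' a zero denominator yields 0 with a warning. The per-class accuracy column
#' equals recall (the within-class hit rate, as conventional in per-class
#' performance tables).
#'
#' @param confusion Square count matrix (rows true, columns predicted).
#' @param class_names Optional class labels.
#' @return List with `confusion`, `accuracy` (micro) and a data frame
#'   `per_class` (class, accuracy, precision, recall).
#' @export
per_class_metrics <- function(confusion, class_names = NULL) {
  C <- nrow(confusion)
  stopifnot(ncol(confusion) == C)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(C))
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  safe_div <- function(a, b, what) {
    out <- ifelse(b > 0, a / pmax(b, 1), 0)
    if (any(b == 0)) warning("zero denominator in ", what, "; reporting 0")
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  list(confusion = confusion,
       accuracy = micro_accuracy(confusion),
       per_class = data.frame(class = class_names, accuracy = recall,
                              precision = precision, recall = recall))
}

#' Evaluate a model on a labeled image set
#'
#' Side-effect-free and deterministic: a forward pass in evaluation mode
#' followed by the classification report.
#'
#' @param model A trained model.
#' @param x Image array (H, W, 3, N), normalized.
#' @param y Integer labels in 1..C.
#' @param class_names Optional class labels.
#' @param batch_size Evaluation batch size.
#' @return A classification report as from [per_class_metrics()].
#' @export
evaluate <- function(model, x, y, class_names = NULL, batch_size = 32L) {
  N <- dim(x)[4]
  C <- model$cfg$num_classes
  pred <- integer(N)
  for (s in seq(1L, N, by = batch_size)) {
    e <- min(s + batch_size - 1L, N)
    pred[s:e] <- model_predict(model, x[, , , s:e, drop = FALSE], type = "class")
  }
  per_class_metrics(confusion_matrix(y, pred, C), class_names)
}
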
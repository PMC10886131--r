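# Dice-loss training with Adam. Defaults follow the published protocol:
# 100 epochs, batch 4, learning rate 0.001, beta1 ("momentum") 0.9, weight
# decay 1e-4, random initialization (no pretraining).

#' Training configuration
#'
#' @param epochs number of passes over the training split.
#' @param batch_size images per optimization step.
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decay rates ("momentum 0.9" maps to
#'   `beta1`).
#' @param weight_decay L2 penalty added to gradients ("decay rate 1e-4").
#' @param loss loss name; only `"dice"` is implemented.
#' @param seed seed controlling initialization, shuffling and batching.
#' @param device `"cpu"` (the only backend).
#' @param checkpoint_dir where `last.rds`/`best.rds` and the history log are
#'   written; `NULL` disables checkpointing.
#' @param include_background include class 0 in the Dice mean.
#' @param input_size side to which samples are resized when loaded; `NULL`
#'   keeps the stored resolution.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 4L, learning_rate = 0.001,
                         beta1 = 0.9, beta2 = 0.999, weight_decay = 1e-4,
                         loss = "dice", seed = 1L, device = "cpu",
                         checkpoint_dir = NULL, include_background = TRUE,
                         input_size = NULL) {
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0 || weight_decay < 0)
    rds_spec_error("train_config: epochs, batch_size, learning_rate must be positive")
  if (!identical(loss, "dice")) rds_spec_error("train_config: only the dice loss is implemented")
  if (!device %in% c("cpu", "accelerator")) rds_spec_error("train_config: unknown device")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, loss = loss, seed = as.integer(seed),
                 device = device, checkpoint_dir = checkpoint_dir,
                 include_background = isTRUE(include_background),
                 input_size = input_size),
            class = "train_config")
}

#' Multiclass soft Dice loss
#'
#' Softmax over the class axis, then per-class soft Dice
#' `d_k = (2 sum(p_k t_k) + eps) / (sum(p_k) + sum(t_k) + eps)` against the
#' one-hot truth, summed over all pixels of the batch; the loss is `1 -
#' mean_k d_k`. Lies in `[0, 1]`.
#'
#' @param logits `(H, W, K, N)` or `(H, W, K)` array.
#' @param truth `(H, W, N)` or `(H, W)` integer array of 0-based class
#'   indices (< K).
#' @param eps Dice smoothing constant.
#' @param include_background include class 0 in the mean.
#' @return scalar loss.
#' @export
dice_loss <- function(logits, truth, eps = 1e-6, include_background = TRUE) {
  if (length(dim(logits)) == 3L) logits <- array(logits, dim = c(dim(logits), 1L))
  ag_dice_loss(ag_node(logits), truth, eps, include_background)$value
}

adam_new <- function(params) {
  opt <- new.env(parent = emptyenv())
  opt$t <- 0L
  opt$m <- lapply(params, function(p) p$value * 0)
  opt$v <- lapply(params, function(p) p$value * 0)
  opt
}

# in-place compiled update: parameter values and moment buffers are owned
# exclusively by the registry/optimizer, so no R-level copies are made
adam_step <- function(reg, opt, config) {
  opt$t <- opt$t + 1L
  b1 <- config$beta1; b2 <- config$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (nm in names(reg$params)) {
    p <- reg$params[[nm]]
    if (is.null(p$grad)) next
    cpp_adam_update(p$value, p$grad, opt$m[[nm]], opt$v[[nm]],
                    config$learning_rate, b1, b2, 1e-8,
                    config$weight_decay, corr1, corr2)
    p$grad <- NULL # free gradient storage eagerly
  }
}

# per-channel normalization constants from a list of scenes
norm_constants <- function(scenes) {
  acc <- vapply(scenes, function(s) {
    v <- s$image / 255
    c(colMeans(matrix(v, ncol = 3)), colMeans(matrix(v^2, ncol = 3)))
  }, numeric(6))
  mu <- rowMeans(acc)[1:3]
  sd <- sqrt(pmax(rowMeans(acc)[4:6] - mu^2, 1e-6))
  list(mean = mu, sd = sd)
}

normalize_batch <- function(scenes, norm) {
  H <- nrow(scenes[[1]]$mask); W <- ncol(scenes[[1]]$mask)
  n <- length(scenes)
  x <- array(0, dim = c(H, W, 3L, n))
  t <- array(0L, dim = c(H, W, n))
  for (i in seq_len(n)) {
    x[, , , i] <- sweep(sweep(scenes[[i]]$image / 255, 3, norm$mean), 3, norm$sd, "/")
    t[, , i] <- scenes[[i]]$mask
  }
  list(x = x, truth = t)
}

load_split_scenes <- function(index, split, size) {
  ids <- split_ids(index, split)
  lapply(ids, function(id) load_sample(index, id, size = size))
}

#' Evaluate a model on a list of scenes
#'
#' @param model an `rds_model` with normalization constants set.
#' @param scenes list of [labeled_scene()]s.
#' @param include_background include class 0 in the Dice mean of the loss.
#' @param batch_size evaluation batch size.
#' @return list with `loss`, `miou`, `precision`, `recall` and the pooled
#'   confusion matrix `cm`.
#' @export
evaluate_model <- function(model, scenes, include_background = TRUE, batch_size = 4L) {
  norm <- model$norm_const
  if (is.null(norm)) rds_spec_error("evaluate_model: model has no normalization constants (untrained?)")
  cm <- empty_confusion(model$variant$n_classes)
  total_loss <- 0
  n_done <- 0L
  i <- 1L
  while (i <= length(scenes)) {
    j <- min(i + batch_size - 1L, length(scenes))
    b <- normalize_batch(scenes[i:j], norm)
    lg <- forward(model, b$x, training = FALSE)
    total_loss <- total_loss + dice_loss(lg, b$truth, include_background = include_background) * (j - i + 1L)
    d <- dim(lg)
    cls <- max.col(matrix(aperm(lg, c(1, 2, 4, 3)), ncol = d[3]), ties.method = "first") - 1L
    cm <- accumulate_confusion(array(cls, dim = c(d[1], d[2], d[4])), b$truth, cm)
    n_done <- n_done + (j - i + 1L)
    i <- j + 1L
  }
  pr <- precision_recall(cm)
  list(loss = total_loss / n_done, miou = miou(cm),
       precision = pr$precision, recall = pr$recall, cm = cm)
}

# last.rds carries optimizer moments + RNG for exact resumption; best.rds is
# weights-only (evaluation use). compress = FALSE: checkpoints are large and
# written on the training path.
save_checkpoint <- function(path, model, opt, config, epoch, history, best_miou,
                            with_optimizer = TRUE) {
  ck <- list(state = model_state(model), config = config, epoch = epoch,
             history = history, best_miou = best_miou)
  if (with_optimizer) {
    ck$adam <- list(t = opt$t, m = opt$m, v = opt$v)
    ck$rng <- get(".Random.seed", envir = globalenv())
  }
  saveRDS(ck, path, compress = FALSE)
}

#' Train a segmentation model
#'
#' Seeded end-to-end: initialization, shuffling and batching all derive from
#' `config$seed`. Writes `last.rds` every epoch and `best.rds` whenever the
#' validation mean IoU improves (training loss when there is no validation
#' split); training is resumable from a `last.rds` checkpoint, which restores
#' weights, optimizer moments and the RNG stream.
#'
#' @param model an `rds_model`, a [model_variant()], a preset name, or a
#'   previous `rds_train_result` to continue in memory (equivalent to one
#'   uninterrupted run with more epochs); ignored when `resume_from` is
#'   given.
#' @param data a `rds_dataset_index` with non-empty train (and usually val)
#'   splits.
#' @param config a [train_config()].
#' @param resume_from path to a `last.rds` checkpoint to continue from.
#' @return list of class `rds_train_result` with `model`, `history` (one row
#'   per epoch) and `best_epoch`.
#' @export
train <- function(model, data, config = train_config(), resume_from = NULL) {
  train_scenes <- load_split_scenes(data, "train", config$input_size)
  val_scenes <- load_split_scenes(data, "val", config$input_size)
  if (length(train_scenes) == 0) rds_spec_error("train: training split is empty")

  history <- data.frame()
  best_miou <- -Inf
  start_epoch <- 1L
  opt <- NULL

  if (!is.null(resume_from)) {
    if (!file.exists(resume_from)) rds_io_error(sprintf("checkpoint not found: %s", resume_from))
    ck <- readRDS(resume_from)
    if (is.null(ck$adam)) rds_io_error("checkpoint has no optimizer state; resume from last.rds")
    model <- build_model(ck$state$variant)
    for (nm in names(ck$state$params)) # take ownership, no copies kept in ck
      model$reg$params[[nm]]$value <- ck$state$params[[nm]]
    for (nm in names(ck$state$states)) {
      model$reg$states[[nm]]$mean <- ck$state$states[[nm]]$mean
      model$reg$states[[nm]]$var <- ck$state$states[[nm]]$var
    }
    model$norm_const <- ck$state$norm_const
    opt <- new.env(parent = emptyenv())
    opt$t <- ck$adam$t
    opt$m <- ck$adam$m
    opt$v <- ck$adam$v
    history <- ck$history
    best_miou <- ck$best_miou
    start_epoch <- ck$epoch + 1L
    assign(".Random.seed", ck$rng, envir = globalenv())
    ck <- NULL # the moment/weight buffers now belong to the model/optimizer
    gc(FALSE)
  } else if (inherits(model, "rds_train_result")) {
    # continue a finished run in memory: same weights, optimizer moments and
    # RNG stream, so chunked calls reproduce one long run exactly
    prev <- model
    model <- prev$model
    opt <- prev$opt
    history <- prev$history
    best_miou <- prev$best_miou
    start_epoch <- max(history$epoch) + 1L
  } else {
    set.seed(config$seed)
    if (is.character(model) || inherits(model, "model_variant")) model <- build_model(model)
    model$norm_const <- norm_constants(train_scenes)
    opt <- adam_new(model$reg$params)
  }

  ckdir <- config$checkpoint_dir
  if (!is.null(ckdir)) dir.create(ckdir, recursive = TRUE, showWarnings = FALSE)

  n <- length(train_scenes)
  for (epoch in seq(start_epoch, length.out = max(0L, config$epochs - start_epoch + 1L))) {
    t0 <- proc.time()[["elapsed"]]
    ord <- sample(n)
    ep_loss <- 0
    step <- 0L
    i <- 1L
    while (i <= n) {
      j <- min(i + config$batch_size - 1L, n)
      b <- normalize_batch(train_scenes[ord[i:j]], model$norm_const)
      logits <- model$forward_node(ag_node(b$x), training = TRUE)
      loss <- ag_dice_loss(logits, b$truth, include_background = config$include_background)
      step <- step + 1L
      if (!is.finite(loss$value))
        rds_divergence_error(sprintf("non-finite training loss at epoch %d, step %d", epoch, step))
      ag_zero_grads(model$reg$params)
      ag_backward(loss)
      adam_step(model$reg, opt, config)
      ep_loss <- ep_loss + loss$value * (j - i + 1L)
      i <- j + 1L
    }
    row <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                      val_loss = NA_real_, val_miou = NA_real_,
                      val_precision = NA_real_, val_recall = NA_real_,
                      seconds = NA_real_)
    score <- -row$train_loss
    if (length(val_scenes) > 0) {
      ev <- evaluate_model(model, val_scenes, config$include_background, config$batch_size)
      row$val_loss <- ev$loss
      row$val_miou <- ev$miou
      row$val_precision <- ev$precision
      row$val_recall <- ev$recall
      score <- ev$miou
    }
    row$seconds <- proc.time()[["elapsed"]] - t0
    history <- rbind(history, row)
    gc(FALSE) # large parameter/moment arrays: keep the heap compact
    if (!is.null(ckdir)) {
      if (score > best_miou) {
        best_miou <- score
        save_checkpoint(file.path(ckdir, "best.rds"), model, opt, config, epoch,
                        history, best_miou, with_optimizer = FALSE)
      }
      utils::write.table(history, file.path(ckdir, "history.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    } else if (score > best_miou) best_miou <- score
    last_epoch <- epoch
  }
  if (!is.null(ckdir) && exists("last_epoch", inherits = FALSE))
    save_checkpoint(file.path(ckdir, "last.rds"), model, opt, config, last_epoch,
                    history, best_miou)
  best_epoch <- if (nrow(history) && any(!is.na(history$val_miou)))
    history$epoch[which.max(history$val_miou)] else nrow(history)
  structure(list(model = model, history = history, best_epoch = best_epoch,
                 config = config, opt = opt, best_miou = best_miou),
            class = "rds_train_result")
}

#' Load a trained model from a checkpoint
#' @param path checkpoint file (`last.rds` or `best.rds`).
#' @return an `rds_model` with restored weights.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) rds_io_error(sprintf("checkpoint not found: %s", path))
  ck <- readRDS(path)
  load_model_state(build_model(ck$state$variant), ck$state)
}

#' @export
print.rds_train_result <- function(x, ...) {
  h <- x$history
  cat(sprintf("trained %d epoch(s); final train loss %.4f", nrow(h), h$train_loss[nrow(h)]))
  if (any(!is.na(h$val_miou)))
    cat(sprintf("; best val MIoU %.4f (epoch %d)", max(h$val_miou, na.rm = TRUE), x$best_epoch))
  cat("\n")
  invisible(x)
}
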
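#' @title Training and evaluation
#' @description Adam optimisation with linear warm-up and cosine
#'   annealing, early stopping and checkpointing on validation Dice, plus
#'   evaluation and the inference-timing protocol.
#' @name training
NULL

#' Training configuration
#'
#' @param lr0 initial (peak) learning rate.
#' @param lr_min floor of the cosine schedule.
#' @param warmup_epochs epochs of linear warm-up to `lr0`.
#' @param max_epochs maximum number of epochs.
#' @param patience early-stopping patience on validation Dice.
#' @param batch_size minibatch size (8 standard; 4 is the convention for
#'   the full-width variant, set `full = TRUE`).
#' @param full flag marking the full-width variant (switches the default
#'   batch size to 4).
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param weight_decay L2 coefficient added to the gradients.
#' @param threshold binarisation threshold for the validation Dice.
#' @param seed integer seed controlling shuffling.
#' @param loss a [loss_config()].
#' @return an object of class `fg_train_config`.
#' @export
train_config <- function(lr0 = 1e-4, lr_min = 1e-6, warmup_epochs = 5L,
                         max_epochs = 30L, patience = 5L,
                         batch_size = if (full) 4L else 8L, full = FALSE,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         weight_decay = 1e-4, threshold = 0.5, seed = 1L,
                         loss = loss_config()) {
  stopifnot(lr_min < lr0, patience <= max_epochs, batch_size >= 1L)
  structure(list(lr0 = lr0, lr_min = lr_min,
                 warmup_epochs = as.integer(warmup_epochs),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 weight_decay = weight_decay, threshold = threshold,
                 seed = as.integer(seed), loss = loss),
            class = "fg_train_config")
}

#' Learning rate at a given epoch
#'
#' Epochs `0 .. warmup-1` ramp linearly as `lr0 * (epoch + 1) / warmup`;
#' afterwards the rate follows `lr_min + 0.5 * (lr0 - lr_min) *
#' (1 + cos(pi * t))` with `t` the elapsed fraction of the post-warm-up
#' span, reaching `lr_min` at the final epoch. Both pieces equal `lr0`
#' at the junction, so the schedule is continuous.
#'
#' @param epoch zero-based epoch index in `[0, max_epochs)`.
#' @param cfg an `fg_train_config`.
#' @return learning rate.
#' @export
lr_at <- function(epoch, cfg) {
  if (epoch < 0 || epoch >= cfg$max_epochs) stop("epoch out of range")
  if (epoch < cfg$warmup_epochs)
    return(cfg$lr0 * (epoch + 1) / cfg$warmup_epochs)
  span <- cfg$max_epochs - cfg$warmup_epochs
  t <- if (span <= 1) 1 else (epoch - cfg$warmup_epochs) / (span - 1)
  cfg$lr_min + 0.5 * (cfg$lr0 - cfg$lr_min) * (1 + cos(pi * t))
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- fg_tree_map(params, function(x, nm) {
    y <- x; y[] <- 0; y
  })
  list(m = zeros, v = zeros, t = 0L)
}

# one Adam step over the parameter tree (buffers skipped); weight decay
# is added to the raw gradient (coupled L2)
adam_step <- function(params, grads, state, lr, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  walk <- function(p, g, m, v, name) {
    if (fg_is_leaf(p)) {
      if (is.null(g) || name %in% .fg_buffer_names)
        return(list(p = p, m = m, v = v))
      g <- g + cfg$weight_decay * p
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + cfg$adam_eps)
      return(list(p = p, m = m, v = v))
    }
    nms <- fg_node_names(p)
    for (k in seq_along(p)) {
      if (is.null(p[[k]])) next
      r <- walk(p[[k]], g[[k]], m[[k]], v[[k]], nms[k])
      p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
    }
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v, "")
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# ---- batching helpers -------------------------------------------------------

# stack a list of preprocessed pairs (x [C,H,W], y [H,W]) into internal
# tensors [H,W,B,C] / [H,W,B,1]
stack_batch <- function(pairs) {
  B <- length(pairs)
  d <- dim(pairs[[1]]$x)
  x <- array(0, c(d[2], d[3], B, d[1]))
  y <- array(0, c(d[2], d[3], B, 1L))
  for (b in seq_len(B)) {
    x[, , b, ] <- aperm(pairs[[b]]$x, c(2, 3, 1))
    y[, , b, 1] <- pairs[[b]]$y
  }
  list(x = x, y = y)
}

# ---- training loop ----------------------------------------------------------

#' Train a model
#'
#' Runs Adam with the configured warm-up + cosine schedule, computing the
#' macro validation Dice (threshold `cfg$threshold`) after every epoch.
#' Training stops when validation Dice has not improved (strict increase
#' by more than 1e-6) for `patience` epochs, or at `max_epochs`. The best
#' checkpoint (maximum validation Dice) is retained with a full copy of
#' the weights.
#'
#' @param model an `fg_model`.
#' @param train_pairs,val_pairs lists of preprocessed pairs (`x`
#'   `[C,H,W]`, `y` `[H,W]`), e.g. from [preprocess_sample()].
#' @param cfg an `fg_train_config`.
#' @param augment optional function `pair -> pair` applied to each
#'   training pair at every epoch (e.g. wrapping [augment_sample()]).
#' @param verbose print per-epoch progress.
#' @param stop_dice optional convergence target: stop as soon as the
#'   validation Dice reaches this value (used e.g. by overfitting sanity
#'   checks; `NULL` disables it).
#' @return list with `best` (a checkpoint record: `epoch`, `val_dice`,
#'   `params`, `config`) and `history` (data frame with per-epoch train
#'   loss, val loss, val Dice and learning rate).
#' @export
train_model <- function(model, train_pairs, val_pairs, cfg = train_config(),
                        augment = NULL, verbose = FALSE, stop_dice = NULL) {
  stopifnot(inherits(model, "fg_model"), inherits(cfg, "fg_train_config"))
  if (length(train_pairs) == 0L || length(val_pairs) == 0L)
    stop("empty training or validation split")
  set.seed(cfg$seed)
  state <- adam_init(model$params)
  hist <- list()
  best <- list(epoch = NA_integer_, val_dice = -Inf, params = NULL)
  wait <- 0L
  n <- length(train_pairs)
  for (epoch in seq_len(cfg$max_epochs) - 1L) {
    lr <- lr_at(epoch, cfg)
    ord <- sample(n)
    losses <- c()
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      pairs <- train_pairs[idx]
      if (!is.null(augment)) pairs <- lapply(pairs, augment)
      bt <- stack_batch(pairs)
      fw <- model_fwd(model, bt$x, train = TRUE, keep = TRUE)
      model <- fw$model
      lg <- batch_loss_grad(bt$y, fw$y, cfg$loss)
      if (!is.finite(lg$loss))
        stop(sprintf("non-finite loss (%f) at epoch %d; aborting", lg$loss,
                     epoch))
      bw <- model_bwd(model, fw$caches, lg$grad)
      st <- adam_step(model$params, bw$grads, state, lr, cfg)
      model$params <- st$params
      state <- st$state
      losses <- c(losses, lg$loss)
    }
    ev <- evaluate_model(model, val_pairs, threshold = cfg$threshold)
    val_dice <- ev$macro$dice["mean"][[1]]
    hist[[length(hist) + 1L]] <- data.frame(
      epoch = epoch, train_loss = mean(losses), val_loss = ev$mean_loss,
      val_dice = val_dice, lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  train %.4f  val dice %.4f",
                      epoch, lr, mean(losses), val_dice))
    if (!is.null(stop_dice) && val_dice >= stop_dice) {
      best <- list(epoch = epoch, val_dice = val_dice, params = model$params,
                   config = model$config)
      break
    }
    if (val_dice > best$val_dice + 1e-6) {
      best <- list(epoch = epoch, val_dice = val_dice, params = model$params,
                   config = model$config)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  list(best = best, history = do.call(rbind, hist), model = model)
}

#' Evaluate a model on a list of samples
#'
#' Forward pass in evaluation mode, thresholding, pixel confusion counts
#' and the five metrics per image; reports the macro (per-image mean ±
#' sd) and micro (pooled-pixel) summaries.
#'
#' @param model an `fg_model`.
#' @param pairs list of preprocessed pairs.
#' @param threshold binarisation threshold.
#' @param loss_cfg a [loss_config()] used for the reported mean loss.
#' @param batch_size forward-pass batch size (throughput only; the
#'   reported per-image metrics are unaffected).
#' @return list with `per_image` (data frame), `macro` (mean and sd per
#'   metric), `micro` (metrics on pooled counts) and `mean_loss`.
#' @export
evaluate_model <- function(model, pairs, threshold = 0.5,
                           loss_cfg = loss_config(), batch_size = 8L) {
  if (length(pairs) == 0L) stop("empty sample list")
  rows <- vector("list", length(pairs))
  pooled <- list(tp = 0, fp = 0, tn = 0, fn = 0)
  losses <- numeric(length(pairs))
  for (start in seq(1L, length(pairs), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(pairs))
    bt <- stack_batch(pairs[idx])
    yb <- model_fwd(model, bt$x, train = FALSE)$y
    for (b in seq_along(idx)) {
      i <- idx[b]
      p <- pairs[[i]]
      yhat <- matrix(yb[, , b, 1], dim(yb)[1], dim(yb)[2])
      losses[i] <- compound_loss(p$y, yhat, loss_cfg)
      pred <- binarize(yhat, threshold)
      cc <- confusion_counts(p$y, pred)
      for (nm in names(pooled)) pooled[[nm]] <- pooled[[nm]] + cc[[nm]]
      m <- segmentation_metrics(cc)
      rows[[i]] <- data.frame(id = p$id %||% as.character(i),
                              dice = m$dice, iou = m$iou,
                              precision = m$precision, recall = m$recall,
                              accuracy = m$accuracy)
    }
  }
  per_image <- do.call(rbind, rows)
  macro <- lapply(per_image[, -1], function(v)
    c(mean = mean(v), sd = stats::sd(v)))
  list(per_image = per_image, macro = macro,
       micro = segmentation_metrics(pooled), mean_loss = mean(losses))
}

# ---- checkpointing ----------------------------------------------------------

#' Save / load a checkpoint record
#'
#' A checkpoint stores the epoch, the validation Dice recorded when it
#' was taken, the complete weight tree and the model configuration; the
#' round-trip is byte-exact.
#'
#' @param record checkpoint list (as in the `best` field of
#'   [train_model()]'s result).
#' @param path file path.
#' @export
save_checkpoint <- function(record, path) {
  saveRDS(record, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}

#' Restore checkpointed weights into a model
#' @param model an `fg_model` built from the same configuration.
#' @param record a checkpoint record.
#' @return the model with restored weights.
#' @export
restore_checkpoint <- function(model, record) {
  stopifnot(inherits(model, "fg_model"))
  model$params <- record$params
  model
}

# ---- timing -----------------------------------------------------------------

#' Measure mean inference time per image
#'
#' Two warm-up passes followed by `n` timed forward passes at batch size
#' 1. Wall-clock timings are hardware dependent and reported for context
#' only.
#'
#' @param model an `fg_model`.
#' @param input_shape `c(channels, H, W)`.
#' @param n number of timed passes (default 10).
#' @return list with `mean_ms` and the vector of `timings_ms`.
#' @export
measure_inference_time <- function(model, input_shape = c(3L, 64L, 64L),
                                   n = 10L) {
  x <- array(stats::runif(prod(input_shape)), input_shape)
  for (i in 1:2) predict(model, x)
  times <- numeric(n)
  for (i in seq_len(n)) {
    t0 <- Sys.time()
    predict(model, x)
    times[i] <- as.numeric(difftime(Sys.time(), t0, units = "secs")) * 1000
  }
  list(mean_ms = mean(times), timings_ms = times)
}

#' Analytic multiply-accumulate count of a configuration's forward pass
#'
#' Counts the multiply-accumulates of all convolutions, transposed
#' convolutions and MLP projections for one image; used alongside
#' wall-clock timings for context.
#'
#' @param config an `fg_config`.
#' @param image_size input side in pixels.
#' @return total multiply-accumulate count.
#' @export
count_flops <- function(config, image_size = 256L) {
  ec <- config$encoder_channels; dc <- config$decoder_channels
  sizes <- image_size / c(1L, 2L, 4L, 8L, 16L)
  total <- 0
  c_in <- config$input_channels
  for (i in 1:5) {
    hw <- sizes[i]^2
    total <- total + hw * 9 * c_in * ec[i]
    if (config$use_stmlp)
      total <- total + 2 * hw * 2 * ec[i] * config$hidden_ratio * ec[i]
    if (config$use_cbam) {
      bott <- max(1, ec[i] %/% config$cbam_reduction)
      total <- total + 2 * 2 * ec[i] * bott + hw * 49 * 2
    }
    c_in <- ec[i]
  }
  d_in <- ec[5]
  for (j in 1:4) {
    hw <- sizes[5 - j]^2
    total <- total + hw * 4 * d_in * dc[j]
    if (config$use_ag) {
      ic <- max(1, ec[5 - j] %/% 2)
      total <- total + hw * (ec[5 - j] * ic + dc[j] * ic + ic)
    }
    total <- total + hw * 9 * (2 * dc[j]) * dc[j] + hw * 9 * dc[j] * dc[j]
    d_in <- dc[j]
  }
  total + image_size^2 * dc[4] * config$out_channels
}
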
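# Generic model training: subject-level 6:2:2 splitting, class balancing,
# Adam with a plateau learning-rate schedule, best-validation checkpointing.

#' Training configuration
#'
#' Defaults mirror the study protocol: Adam with default moments, initial
#' learning rate 5e-5 halved after 3 consecutive epochs without a new
#' validation-loss minimum, 50 epochs, mini-batch size 1024, subject-level
#' 6:2:2 split, class balancing on.
#'
#' @param lr Initial learning rate.
#' @param plateau_factor Multiplier applied on plateau (0.5 = halve).
#' @param patience Consecutive non-improving epochs before reduction.
#' @param max_epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param ratio Train/validation/test split ratio, positive, summing to 10.
#' @param balance Downsample the majority class before training.
#' @param seed RNG seed for initialization, shuffling and balancing.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 5e-5, plateau_factor = 0.5, patience = 3L,
                         max_epochs = 50L, batch_size = 1024L,
                         ratio = c(6, 2, 2), balance = TRUE, seed = 1L) {
  if (length(ratio) != 3 || any(ratio <= 0) || sum(ratio) != 10)
    stop("ratio must be three positive parts summing to 10")
  if (patience < 1) stop("patience must be >= 1")
  structure(list(optimizer = "adam", lr = lr, plateau_factor = plateau_factor,
                 patience = as.integer(patience), max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), ratio = ratio,
                 balance = balance, seed = as.integer(seed)),
            class = "train_config")
}

#' Subject-level train/validation/test split
#'
#' Subjects (not beats or records) are partitioned so no subject appears in
#' two partitions; partition sizes follow the ratio by largest-remainder
#' allocation, so each is within one subject of the exact proportion.
#'
#' @param records Data frame with a `subject_id` column (e.g. the `records`
#'   table of a `beat_set`), or a character vector of subject ids.
#' @param ratio Three positive parts summing to 10.
#' @param seed RNG seed.
#' @return List with character vectors `train`, `validation`, `test`.
#' @export
split_dataset <- function(records, ratio = c(6, 2, 2), seed = 1L) {
  subjects <- if (is.character(records)) unique(records) else unique(records$subject_id)
  n <- length(subjects)
  if (n < 3) stop("need at least as many subjects as partitions (3)")
  if (length(ratio) != 3 || any(ratio <= 0) || sum(ratio) != 10)
    stop("ratio must be three positive parts summing to 10")
  exact <- n * ratio / 10
  sizes <- floor(exact)
  rem <- n - sum(sizes)
  if (rem > 0) {
    order_frac <- order(exact - sizes, decreasing = TRUE)
    sizes[order_frac[seq_len(rem)]] <- sizes[order_frac[seq_len(rem)]] + 1L
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  shuffled <- sample(subjects)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  list(train = shuffled[seq_len(sizes[1])],
       validation = shuffled[sizes[1] + seq_len(sizes[2])],
       test = shuffled[sizes[1] + sizes[2] + seq_len(sizes[3])])
}

#' Balance beat classes by downsampling
#'
#' Randomly downsamples the majority class so hyperkalemic and normokalemic
#' beat counts are equal. Deterministic given the seed; an already balanced
#' set is returned unchanged (same multiset of beats).
#'
#' @param bs A `beat_set`.
#' @param seed RNG seed.
#' @return A balanced `beat_set`.
#' @export
balance_classes <- function(bs, seed = 1L) {
  lab <- bs$meta$label
  n_h <- sum(lab == "hyper"); n_n <- sum(lab == "normo")
  if (n_h == 0 || n_n == 0) stop("both classes must be present to balance")
  if (n_h == n_n) return(bs)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  keep_n <- min(n_h, n_n)
  idx_h <- which(lab == "hyper"); idx_n <- which(lab == "normo")
  if (n_h > keep_n) idx_h <- sort(sample(idx_h, keep_n))
  if (n_n > keep_n) idx_n <- sort(sample(idx_n, keep_n))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  beat_subset(bs, sort(c(idx_h, idx_n)))
}

#' Plateau learning-rate schedule
#'
#' The rate is multiplied by `plateau_factor` whenever `patience`
#' consecutive epochs pass without a new minimum of the monitored loss;
#' the counter resets on improvement and after each reduction.
#'
#' @param losses Per-epoch monitored (validation) losses observed so far.
#' @param config A [train_config()].
#' @return Numeric vector of length `length(losses) + 1`: the learning rate
#'   in effect during each epoch, including the upcoming one.
#' @export
lr_schedule <- function(losses, config = train_config()) {
  lr <- config$lr
  out <- numeric(length(losses) + 1L)
  best <- Inf; counter <- 0L
  for (t in seq_along(losses)) {
    out[t] <- lr
    if (losses[t] < best) {
      best <- losses[t]; counter <- 0L
    } else {
      counter <- counter + 1L
      if (counter >= config$patience) {
        lr <- lr * config$plateau_factor
        counter <- 0L
      }
    }
  }
  out[length(losses) + 1L] <- lr
  out
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, state, lr, skip = character(0)) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    if (nm %in% skip) next
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + state$eps)
  }
  list(params = params, state = state)
}

# evaluation-mode loss/accuracy over a beat matrix
eval_beats <- function(model, X, y, batch_size = 512L) {
  n <- nrow(X)
  loss <- 0; correct <- 0
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batch_size - 1L)
    fw <- nn_forward(model, X[i:j, , drop = FALSE], training = FALSE)
    sx <- softmax_xent(fw$logits, y[i:j])
    loss <- loss + sx$loss * (j - i + 1L)
    correct <- correct + sum(max.col(fw$probs) - 1L == y[i:j])
    i <- j + 1L
  }
  list(loss = loss / n, accuracy = correct / n)
}

training_failure <- function(message, log) {
  stop(errorCondition(message, class = "training_failure", log = log))
}

# Shared minibatch training loop (generic pretraining and personal
# fine-tuning). Frozen parameters are never updated; frozen stages run
# their batch norms in evaluation mode (see bn_is_training).
fit_model <- function(model, X, y, epochs, lr, batch_size, seed,
                      Xval = NULL, yval = NULL, config = NULL,
                      track_best = FALSE) {
  frozen <- frozen_param_names(model)
  adam <- adam_init(model$params)
  set.seed(seed)
  log <- data.frame(epoch = integer(0), lr = numeric(0), train_loss = numeric(0),
                    val_loss = numeric(0), val_accuracy = numeric(0))
  best <- list(loss = Inf, params = model$params, buffers = model$buffers, epoch = 0L)
  cur_lr <- lr
  best_seen <- Inf; counter <- 0L
  n <- nrow(X)
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    i <- 1L
    while (i <= n) {
      j <- min(n, i + batch_size - 1L)
      idx <- ord[i:j]
      fw <- nn_forward(model, X[idx, , drop = FALSE], training = TRUE, collect = TRUE)
      model$buffers <- fw$buffers
      sx <- softmax_xent(fw$logits, y[idx])
      if (!is.finite(sx$loss))
        training_failure("non-finite training loss", log)
      bw <- nn_backward(model, fw$cache, sx$dlogits)
      st <- adam_step(model$params, bw$grads, adam, cur_lr, skip = frozen)
      model$params <- st$params; adam <- st$state
      ep_loss <- ep_loss + sx$loss; nb <- nb + 1L
      i <- j + 1L
    }
    if (!is.null(Xval)) {
      ev <- eval_beats(model, Xval, yval)
      log <- rbind(log, data.frame(epoch = epoch, lr = cur_lr, train_loss = ep_loss / nb,
                                   val_loss = ev$loss, val_accuracy = ev$accuracy))
      if (track_best && ev$loss < best$loss)
        best <- list(loss = ev$loss, params = model$params,
                     buffers = model$buffers, epoch = epoch)
      # plateau schedule on the monitored (validation) loss
      if (!is.null(config)) {
        if (ev$loss < best_seen) {
          best_seen <- ev$loss; counter <- 0L
        } else {
          counter <- counter + 1L
          if (counter >= config$patience) {
            cur_lr <- cur_lr * config$plateau_factor
            counter <- 0L
          }
        }
      }
    } else {
      log <- rbind(log, data.frame(epoch = epoch, lr = cur_lr, train_loss = ep_loss / nb,
                                   val_loss = NA_real_, val_accuracy = NA_real_))
    }
  }
  list(model = model, log = log, best = best)
}

labels_to_y <- function(labels) {
  if (!all(labels %in% c("hyper", "normo"))) stop("labels must be hyper/normo")
  as.integer(labels == "hyper")
}

#' Train the generic (pretrained) model
#'
#' Trains on the pooled training beats with Adam, cross-entropy loss and the
#' plateau learning-rate schedule; the returned checkpoint holds the weights
#' of the epoch with minimal validation loss.
#'
#' @param train_bs,val_bs Training and validation `beat_set`s.
#' @param spec A [resnet_spec()].
#' @param config A [train_config()].
#' @return An `ecg_checkpoint`: list with `spec`, `params`, `buffers`,
#'   `freeze` (named logical, all `FALSE`), `meta` (best epoch, its
#'   validation loss, seed) and `log` (per-epoch losses and learning rates).
#' @export
train_generic <- function(train_bs, val_bs, spec = resnet_spec("resnet18_1d"),
                          config = train_config()) {
  if (nrow(train_bs$X) == 0 || nrow(val_bs$X) == 0)
    stop("training and validation beat sets must be non-empty")
  if (config$balance) train_bs <- balance_classes(train_bs, seed = config$seed)
  model <- build_network(spec, seed = config$seed)
  y <- labels_to_y(train_bs$meta$label)
  yval <- labels_to_y(val_bs$meta$label)
  fit <- fit_model(model, train_bs$X, y, epochs = config$max_epochs, lr = config$lr,
                   batch_size = config$batch_size, seed = config$seed,
                   Xval = val_bs$X, yval = yval, config = config, track_best = TRUE)
  new_checkpoint(spec, fit$best$params, fit$best$buffers,
                 meta = list(epoch = fit$best$epoch, val_loss = fit$best$loss,
                             seed = config$seed),
                 log = fit$log)
}

new_checkpoint <- function(spec, params, buffers, meta, log = NULL,
                           freeze = NULL) {
  if (is.null(freeze)) freeze <- stats::setNames(rep(FALSE, length(params)), names(params))
  structure(list(spec = spec, params = params, buffers = buffers,
                 freeze = freeze, meta = meta, log = log),
            class = "ecg_checkpoint")
}

#' @export
print.ecg_checkpoint <- function(x, ...) {
  cat(sprintf("<ecg_checkpoint %s: best epoch %s, val loss %s, %d frozen of %d weights>\n",
              x$spec$variant, x$meta$epoch %||% "?",
              format(x$meta$val_loss %||% NA, digits = 4),
              sum(x$freeze), length(x$freeze)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Instantiate a model from a checkpoint
#'
#' @param ckpt An `ecg_checkpoint`.
#' @return A `resnet1d` model carrying the checkpoint's weights.
#' @export
checkpoint_model <- function(ckpt) {
  structure(list(spec = ckpt$spec, params = ckpt$params, buffers = ckpt$buffers,
                 frozen_stages = 0L),
            class = "resnet1d")
}
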
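# SGD training with momentum, step learning-rate decay and cross-entropy
# loss. The full-scale recipe (90 epochs, lr 0.01 reduced by 0.1 every 30
# epochs, momentum 0.9, batch 128) is the default; desk-scale work shrinks
# epochs and batch while keeping the same schedule shape.

#' Training hyperparameters
#'
#' @param epochs number of epochs.
#' @param batch_size minibatch size.
#' @param lr_initial initial learning rate.
#' @param lr_decay_factor multiplicative step decay factor.
#' @param lr_decay_every decay interval in epochs (epoch e uses
#'   `lr_initial * lr_decay_factor^floor((e-1)/lr_decay_every)`; 90 epochs
#'   with interval 30 gives exactly two decays).
#' @param momentum classical momentum coefficient.
#' @param weight_decay L2 penalty coefficient (default 0).
#' @param seed integer seed controlling shuffling (and dropout, if enabled).
#' @return object of class `train_spec`.
#' @export
train_spec <- function(epochs = 90, batch_size = 128, lr_initial = 0.01,
                       lr_decay_factor = 0.1, lr_decay_every = 30,
                       momentum = 0.9, weight_decay = 0, seed = 1) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_initial = lr_initial, lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 momentum = momentum, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "train_spec")
}

#' Desk-scale training defaults
#'
#' 15 epochs at batch 64, lr 0.01 decayed by 0.1 every 6 epochs (two decays
#' over the run, matching the shape of the full-scale schedule), momentum
#' 0.9.
#'
#' @param seed integer seed.
#' @param epochs number of epochs.
#' @return a [train_spec()].
#' @export
desk_train_spec <- function(seed = 1, epochs = 15) {
  train_spec(epochs = epochs, batch_size = 64, lr_initial = 0.01,
             lr_decay_factor = 0.1, lr_decay_every = 6, momentum = 0.9,
             seed = seed)
}

# Normalize training data into list(x, y, x_eval, y_eval).
.as_train_data <- function(data) {
  if (inherits(data, "shape_dataset")) {
    list(x = data$train$x, y = data$train$y,
         x_eval = data$eval$x, y_eval = data$eval$y)
  } else if (is.character(data)) {
    .as_train_data(load_shape_dataset(data))
  } else if (is.list(data) && !is.null(data$x) && !is.null(data$y)) {
    data
  } else {
    stop("data must be a shape_dataset, a dataset directory, or list(x, y)",
         call. = FALSE)
  }
}

#' Train an N-stream model
#'
#' Stochastic gradient descent with classical momentum and cross-entropy
#' loss. The learning rate follows a step schedule; each epoch logs the
#' learning rate, mean training loss, and top-1/top-5 accuracy on the eval
#' split (when present).
#'
#' @param model a `stream_net` built with [build_model()].
#' @param data a `shape_dataset`, a dataset directory, or
#'   `list(x, y, x_eval, y_eval)` with `x` an (H, W, 3, N) array.
#' @param spec a [train_spec()].
#' @param verbose print one line per epoch.
#' @return list with `model` (trained) and `log` (data.frame of epoch, lr,
#'   train_loss, eval_top1, eval_top5).
#' @export
train <- function(model, data, spec = train_spec(), verbose = FALSE) {
  .assert(inherits(model, "stream_net"), "model must be a stream_net")
  .assert(inherits(spec, "train_spec"), "spec must be a train_spec")
  d <- .as_train_data(data)
  N <- length(d$y)
  .assert(N > 0, "training dataset is empty")
  classes <- sort(unique(d$y))
  .assert(length(classes) <= model$arch$n_classes,
          sprintf("dataset has %d classes but the model outputs %d",
                  length(classes), model$arch$n_classes))
  model$classes <- if (length(classes) == model$arch$n_classes) classes else
    seq_len(model$arch$n_classes)
  y_idx <- .labels_to_idx(model, d$y)

  vel <- .zero_like_params(model)
  log_rows <- vector("list", spec$epochs)
  net <- list(model = model, deleted = list())

  .with_seed(spec$seed, {
    for (epoch in seq_len(spec$epochs)) {
      lr <- spec$lr_initial *
        spec$lr_decay_factor^((epoch - 1) %/% spec$lr_decay_every)
      perm <- sample.int(N)
      losses <- c()
      for (start in seq(1, N, by = spec$batch_size)) {
        bi <- perm[start:min(start + spec$batch_size - 1, N)]
        xb <- d$x[, , , bi, drop = FALSE]
        yb <- y_idx[bi]
        dropout_masks <- NULL
        if (model$arch$fc_dropout > 0) {
          p <- model$arch$fc_dropout
          dropout_masks <- lapply(model$arch$fc_widths, function(w) {
            matrix(stats::rbinom(w * length(bi), 1, 1 - p) / (1 - p),
                   w, length(bi))
          })
        }
        net$model <- model
        fw <- .net_forward(net, xb, cache = TRUE,
                           dropout_masks = dropout_masks)
        ce <- .softmax_ce(fw$logits, yb)
        losses <- c(losses, ce$loss)
        g <- .net_backward(model, fw, ce$dlogits, dropout_masks)
        upd <- .sgd_update(model, vel, g, lr, spec$momentum,
                           spec$weight_decay)
        model <- upd$model
        vel <- upd$vel
      }
      e1 <- e5 <- NA_real_
      if (!is.null(d$x_eval)) {
        net$model <- model
        logits <- predict_logits(net$model, d$x_eval)
        ye <- .labels_to_idx(model, d$y_eval)
        ord <- apply(logits, 2, order, decreasing = TRUE)
        k5 <- min(5, nrow(logits))
        e1 <- mean(ord[1, ] == ye)
        e5 <- mean(vapply(seq_along(ye),
                          function(i) ye[i] %in% ord[seq_len(k5), i],
                          logical(1)))
      }
      log_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                      train_loss = mean(losses),
                                      eval_top1 = e1, eval_top5 = e5)
      if (verbose) {
        message(sprintf("epoch %d  lr %.4g  loss %.4f  top1 %.3f",
                        epoch, lr, mean(losses), e1))
      }
    }
  })
  list(model = model, log = do.call(rbind, log_rows))
}

.zero_like_params <- function(model) {
  list(streams = lapply(model$streams, function(st) {
    lapply(st, function(ly) list(dW = array(0, dim(ly$W)),
                                 db = numeric(length(ly$b))))
  }),
  fc = lapply(model$fc, function(f) list(dW = matrix(0, nrow(f$W), ncol(f$W)),
                                         db = numeric(length(f$b)))))
}

# Backward through FC head and every stream; returns grads shaped like
# .zero_like_params().
.net_backward <- function(model, fw, dlogits, dropout_masks = NULL) {
  nfc <- length(model$fc)
  fc_g <- vector("list", nfc)
  dz <- dlogits
  for (i in rev(seq_len(nfc))) {
    a_prev <- fw$fc_cache[[i]]
    fc_g[[i]] <- list(dW = dz %*% t(a_prev), db = rowSums(dz))
    if (i > 1) {
      da <- t(model$fc[[i]]$W) %*% dz
      if (!is.null(dropout_masks)) da <- da * dropout_masks[[i - 1]]
      dz <- da * (fw$fc_cache[[i]] > 0)
    } else {
      da <- t(model$fc[[i]]$W) %*% dz
    }
  }
  # split concatenated gradient back into streams
  units <- model$arch$stream_units
  stream_g <- vector("list", model$arch$n_streams)
  for (s in seq_len(model$arch$n_streams)) {
    rows <- ((s - 1) * units + 1):(s * units)
    dpool <- da[rows, , drop = FALSE]
    dim(dpool) <- fw$stream_caches[[s]][[length(model$streams[[s]])]]$pooled_dim
    stream_g[[s]] <- .stream_backward(model, s, fw$stream_caches[[s]],
                                      dpool)$grads
  }
  list(streams = stream_g, fc = fc_g)
}

.sgd_update <- function(model, vel, g, lr, momentum, weight_decay) {
  for (s in seq_along(model$streams)) {
    for (l in seq_along(model$streams[[s]])) {
      gW <- g$streams[[s]][[l]]$dW
      if (weight_decay > 0) gW <- gW + weight_decay * model$streams[[s]][[l]]$W
      vel$streams[[s]][[l]]$dW <- momentum * vel$streams[[s]][[l]]$dW - lr * gW
      vel$streams[[s]][[l]]$db <- momentum * vel$streams[[s]][[l]]$db -
        lr * g$streams[[s]][[l]]$db
      model$streams[[s]][[l]]$W <- model$streams[[s]][[l]]$W +
        vel$streams[[s]][[l]]$dW
      model$streams[[s]][[l]]$b <- model$streams[[s]][[l]]$b +
        vel$streams[[s]][[l]]$db
    }
  }
  for (i in seq_along(model$fc)) {
    gW <- g$fc[[i]]$dW
    if (weight_decay > 0) gW <- gW + weight_decay * model$fc[[i]]$W
    vel$fc[[i]]$dW <- momentum * vel$fc[[i]]$dW - lr * gW
    vel$fc[[i]]$db <- momentum * vel$fc[[i]]$db - lr * g$fc[[i]]$db
    model$fc[[i]]$W <- model$fc[[i]]$W + vel$fc[[i]]$dW
    model$fc[[i]]$b <- model$fc[[i]]$b + vel$fc[[i]]$db
  }
  list(model = model, vel = vel)
}
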
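# Forward and backward passes. Activations live as (H, W, F, B) arrays on
# the conv side and (features x batch) matrices on the FC side.

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Forward one stream. `upto` stops at a conv layer and returns its map
# (post-ReLU by default, pre-ReLU with pre_activation = TRUE); otherwise the
# stream's final pooled output is returned. With cache = TRUE all
# intermediates needed for the backward pass are kept.
.stream_forward <- function(model, s, x, upto = NULL, cache = FALSE,
                            pre_activation = FALSE) {
  layers <- model$streams[[s]]
  caches <- if (cache) vector("list", length(layers)) else NULL
  a <- x
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    z <- .conv2d_forward_cpp(a, ly$W, ly$b, ly$stride, ly$padding)
    if (!is.null(upto) && upto == l && pre_activation) {
      return(list(out = z, caches = caches))
    }
    act <- .relu(z)
    if (!is.null(upto) && upto == l) return(list(out = act, caches = caches))
    pooled <- act
    pool_idx <- NULL
    if (ly$pool_after) {
      mp <- .maxpool_forward_cpp(act, ly$pool_size, ly$pool_stride)
      pooled <- mp$out
      pool_idx <- mp$idx
    }
    if (cache) {
      caches[[l]] <- list(x_in = a, mask = z > 0, act_dim = dim(act),
                          pool_idx = pool_idx, pooled_dim = dim(pooled))
    }
    a <- pooled
  }
  list(out = a, caches = caches)
}

# Backward through one stream from the gradient at its final pooled output
# down to (optionally) the input image. Returns per-layer weight grads and dx.
.stream_backward <- function(model, s, caches, d_pooled, need_dx = FALSE) {
  layers <- model$streams[[s]]
  grads <- vector("list", length(layers))
  g <- d_pooled
  for (l in rev(seq_along(layers))) {
    ly <- layers[[l]]
    cc <- caches[[l]]
    if (ly$pool_after) {
      g <- .maxpool_backward_cpp(cc$pool_idx, g, as.integer(cc$act_dim))
    }
    g <- g * cc$mask                      # ReLU gate
    bw <- .conv2d_backward_cpp(cc$x_in, ly$W, g, ly$stride, ly$padding)
    grads[[l]] <- list(dW = bw$dw, db = bw$db)
    if (l > 1 || need_dx) g <- bw$dx else g <- NULL
  }
  list(grads = grads, dx = g)
}

# Apply deletion views to the list of per-stream flattened outputs.
.apply_deletions <- function(flats, deleted) {
  for (d in deleted) {
    s <- d$stream
    if (d$mode == "zero") {
      flats[[s]][] <- 0
    } else {
      flats[[s]][] <- mean(flats[[s]])
    }
  }
  flats
}

# Full forward pass: list(logits (K x B), flats, stream_caches, fc_cache).
.net_forward <- function(net, x, cache = FALSE, dropout_masks = NULL) {
  model <- net$model
  B <- dim(x)[4]
  sc <- vector("list", model$arch$n_streams)
  flats <- vector("list", model$arch$n_streams)
  for (s in seq_len(model$arch$n_streams)) {
    sf <- .stream_forward(model, s, x, cache = cache)
    sc[[s]] <- sf$caches
    flats[[s]] <- matrix(sf$out, ncol = B)
  }
  flats <- .apply_deletions(flats, net$deleted)
  a <- do.call(rbind, flats)
  fc_cache <- list(a)
  nh <- length(model$fc) - 1L
  for (i in seq_len(nh)) {
    a <- .relu(model$fc[[i]]$W %*% a + model$fc[[i]]$b)
    if (!is.null(dropout_masks)) a <- a * dropout_masks[[i]]
    fc_cache[[i + 1L]] <- a
  }
  out <- model$fc[[nh + 1L]]$W %*% a + model$fc[[nh + 1L]]$b
  list(logits = out, flats = flats, stream_caches = sc, fc_cache = fc_cache)
}

# Softmax cross-entropy: loss plus gradient wrt logits (averaged over batch).
.softmax_ce <- function(logits, y_idx) {
  B <- ncol(logits)
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  p <- sweep(e, 2, colSums(e), "/")
  picked <- p[cbind(y_idx, seq_len(B))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dl <- p
  dl[cbind(y_idx, seq_len(B))] <- dl[cbind(y_idx, seq_len(B))] - 1
  list(loss = loss, dlogits = dl / B, probs = p)
}

#' Class scores for a batch of images
#'
#' @param net a `stream_net` or deletion view.
#' @param x (H, W, 3, N) image array (or a single (H, W, 3) image).
#' @param batch_size forward-pass batch size.
#' @return (n_classes x N) matrix of logits.
#' @export
predict_logits <- function(net, x, batch_size = 128) {
  net <- .resolve_net(net)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  .assert(dim(x)[1] == net$model$arch$input_size &&
            dim(x)[2] == net$model$arch$input_size,
          sprintf("images must be %d x %d", net$model$arch$input_size,
                  net$model$arch$input_size))
  N <- dim(x)[4]
  out <- matrix(0, net$model$arch$n_classes, N)
  for (start in seq(1, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, N)
    out[, idx] <- .net_forward(net, x[, , , idx, drop = FALSE])$logits
  }
  out
}

#' Predicted class labels
#'
#' @inheritParams predict_logits
#' @return vector of predicted labels (category ids when the model was
#'   trained on a labeled dataset, otherwise 1-based class indices).
#' @export
predict_classes <- function(net, x, batch_size = 128) {
  model <- .resolve_net(net)$model
  idx <- apply(predict_logits(net, x, batch_size), 2, which.max)
  if (!is.null(model$classes)) model$classes[idx] else idx
}

#' Top-k classification accuracy
#'
#' @inheritParams predict_logits
#' @param y true labels (category ids or class indices).
#' @param k top-k (default 1).
#' @return accuracy in \[0, 1\].
#' @export
top_k_accuracy <- function(net, x, y, k = 1, batch_size = 128) {
  model <- .resolve_net(net)$model
  logits <- predict_logits(net, x, batch_size)
  y_idx <- .labels_to_idx(model, y)
  hits <- vapply(seq_along(y_idx), function(i) {
    topk <- order(logits[, i], decreasing = TRUE)[seq_len(k)]
    y_idx[i] %in% topk
  }, logical(1))
  mean(hits)
}

.labels_to_idx <- function(model, y) {
  if (is.null(model$classes)) return(as.integer(y))
  idx <- match(y, model$classes)
  .assert(!anyNA(idx), "labels contain classes unknown to the model")
  idx
}

#' Activations of one layer of one stream
#'
#' Runs the images through the named stream up to the requested conv layer
#' and returns its activation maps (post-ReLU by default; `pre_activation =
#' TRUE` gives the linear conv output, e.g. for probing convolution
#' linearity on bias-free models).
#'
#' @param net a `stream_net` or deletion view.
#' @param images (H, W, 3, N) array (or one (H, W, 3) image).
#' @param layer_name `"conv1"` ... `"convL"`.
#' @param stream_id stream number.
#' @param pre_activation return pre-ReLU maps.
#' @param batch_size forward batch size.
#' @return (image x filter x y x x) 4-D array.
#' @export
layer_activations <- function(net, images, layer_name = "conv1",
                              stream_id = 1, pre_activation = FALSE,
                              batch_size = 128) {
  net <- .resolve_net(net)
  model <- net$model
  l <- .layer_index(model, layer_name)
  s <- .check_stream(model, stream_id)
  if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1)
  .assert(dim(images)[1] == model$arch$input_size &&
            dim(images)[2] == model$arch$input_size,
          sprintf("images must be %d x %d", model$arch$input_size,
                  model$arch$input_size))
  N <- dim(images)[4]
  res <- NULL
  for (start in seq(1, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, N)
    out <- .stream_forward(model, s, images[, , , idx, drop = FALSE],
                           upto = l, pre_activation = pre_activation)$out
    if (is.null(res)) {
      res <- array(0, dim = c(N, dim(out)[3], dim(out)[1], dim(out)[2]))
    }
    res[idx, , , ] <- aperm(out, c(4, 3, 1, 2))
  }
  res
}
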
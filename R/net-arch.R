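# N-stream fully parallel convolutional classifier. Every stream runs the
# same layer plan (conv + ReLU, optional max-pool) with independent weights
# and no cross-talk; the streams' last pooled outputs are concatenated once
# and fed to the fully connected head.

#' One convolutional layer of the per-stream plan
#'
#' @param n_filters number of filters.
#' @param kernel_size square kernel side.
#' @param stride convolution stride.
#' @param padding zero padding on each side.
#' @param pool_after apply max-pooling after the ReLU.
#' @param pool_size,pool_stride pooling window and stride.
#' @return list describing the layer.
#' @export
conv_layer <- function(n_filters, kernel_size, stride = 1, padding = 0,
                       pool_after = TRUE, pool_size = 2,
                       pool_stride = pool_size) {
  list(n_filters = as.integer(n_filters),
       kernel_size = as.integer(kernel_size), stride = as.integer(stride),
       padding = as.integer(padding), pool_after = isTRUE(pool_after),
       pool_size = as.integer(pool_size), pool_stride = as.integer(pool_stride))
}

#' Architecture of an N-stream fully parallel network
#'
#' Validates the layer plan by propagating spatial dimensions analytically;
#' an inconsistent plan is rejected with the offending layer named. The last
#' convolutional layer must be followed by pooling (the stream-deletion hook
#' operates on each stream's final max-pool output).
#'
#' @param n_streams number of parallel streams (>= 2; a single stream has no
#'   parallel structure to analyse).
#' @param conv_layers list of [conv_layer()] entries shared by all streams.
#' @param input_size input image side in pixels.
#' @param n_classes number of output classes.
#' @param fc_widths widths of the hidden fully connected layers.
#' @param fc_dropout dropout probability in FC hidden layers during training
#'   (default 0 = off).
#' @return object of class `stream_arch` (includes the derived per-layer
#'   spatial sizes in `$sizes`).
#' @export
stream_arch <- function(n_streams, conv_layers, input_size, n_classes,
                        fc_widths = 128, fc_dropout = 0) {
  .assert(n_streams >= 2,
          "n_streams must be >= 2: the parallel analysis is undefined for one stream")
  .assert(length(conv_layers) >= 1, "need at least one conv layer")
  s <- as.integer(input_size)
  sizes <- list()
  for (l in seq_along(conv_layers)) {
    ly <- conv_layers[[l]]
    conv_out <- (s + 2 * ly$padding - ly$kernel_size) %/% ly$stride + 1L
    if (s + 2 * ly$padding < ly$kernel_size || conv_out < 1) {
      stop(sprintf("conv%d: kernel %d exceeds its %d-px (padded) input",
                   l, ly$kernel_size, s + 2 * ly$padding), call. = FALSE)
    }
    pool_out <- conv_out
    if (ly$pool_after) {
      pool_out <- (conv_out - ly$pool_size) %/% ly$pool_stride + 1L
      if (conv_out < ly$pool_size || pool_out < 1) {
        stop(sprintf("conv%d: pooling window %d exceeds its %d-px input",
                     l, ly$pool_size, conv_out), call. = FALSE)
      }
    }
    sizes[[l]] <- list(conv = conv_out, pooled = pool_out)
    s <- pool_out
  }
  last <- conv_layers[[length(conv_layers)]]
  .assert(last$pool_after,
          "the last conv layer must be followed by max-pooling (deletion hook)")
  stream_units <- s^2 * last$n_filters
  structure(list(n_streams = as.integer(n_streams), conv_layers = conv_layers,
                 input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 fc_widths = as.integer(fc_widths), fc_dropout = fc_dropout,
                 sizes = sizes, stream_units = as.integer(stream_units)),
            class = "stream_arch")
}

#' Desk-scale default architecture
#'
#' Two streams of (16 filters 5x5 stride 2 + pool, 32 filters 3x3 + pool) on
#' 64 px input with one 128-wide FC hidden layer: trains in about a minute
#' per instance on one CPU while keeping conv1 kernels large enough (5 px)
#' for the spectral tuning metrics to be meaningful.
#'
#' @param n_classes number of classes (default 20, the desk-scale dataset).
#' @param input_size input side in pixels.
#' @param n_streams number of streams.
#' @return a [stream_arch()].
#' @export
desk_arch <- function(n_classes = 20, input_size = 64, n_streams = 2) {
  stream_arch(
    n_streams = n_streams,
    conv_layers = list(conv_layer(16, 5, stride = 2),
                       conv_layer(32, 3)),
    input_size = input_size, n_classes = n_classes, fc_widths = 128
  )
}

#' Full-scale reference architecture
#'
#' The two-stream fully parallel variant of the classic five-conv-layer
#' network: per stream 48-128-192-192-128 filters (conv1 11x11 stride 4),
#' three max-pool layers, merged into the FC head. Provided for structural
#' fidelity checks; training it requires GPU-scale resources.
#'
#' @param n_streams number of streams.
#' @param n_classes number of classes.
#' @param fc_widths FC hidden widths.
#' @return a [stream_arch()].
#' @export
paper_arch <- function(n_streams = 2, n_classes = 1000,
                       fc_widths = c(4096, 4096)) {
  stream_arch(
    n_streams = n_streams,
    conv_layers = list(
      conv_layer(48, 11, stride = 4, padding = 2, pool_after = TRUE,
                 pool_size = 3, pool_stride = 2),
      conv_layer(128, 5, padding = 2, pool_after = TRUE,
                 pool_size = 3, pool_stride = 2),
      conv_layer(192, 3, padding = 1, pool_after = FALSE),
      conv_layer(192, 3, padding = 1, pool_after = FALSE),
      conv_layer(128, 3, padding = 1, pool_after = TRUE,
                 pool_size = 3, pool_stride = 2)
    ),
    input_size = 224, n_classes = n_classes, fc_widths = fc_widths
  )
}

# Fan-in-scaled uniform initialization U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
.init_mat <- function(n_out, n_in, fan_in) {
  matrix(stats::runif(n_out * n_in, -1, 1) / sqrt(fan_in), n_out, n_in)
}

#' Build a randomly initialized N-stream model
#'
#' Weights are drawn from the fan-in-scaled uniform distribution
#' U(-1/sqrt(fan_in), 1/sqrt(fan_in)); biases start at zero. Construction is
#' deterministic in `seed`.
#'
#' @param arch a [stream_arch()].
#' @param seed integer seed.
#' @return object of class `stream_net`.
#' @export
build_model <- function(arch, seed = 1) {
  .assert(inherits(arch, "stream_arch"), "arch must be a stream_arch")
  .with_seed(seed, {
    streams <- lapply(seq_len(arch$n_streams), function(s) {
      in_ch <- 3L
      lapply(seq_along(arch$conv_layers), function(l) {
        ly <- arch$conv_layers[[l]]
        k <- ly$kernel_size
        fan_in <- k * k * in_ch
        W <- array(stats::runif(k * k * in_ch * ly$n_filters, -1, 1) /
                     sqrt(fan_in),
                   dim = c(k, k, in_ch, ly$n_filters))
        layer <- c(ly, list(W = W, b = numeric(ly$n_filters)))
        in_ch <<- ly$n_filters
        layer
      })
    })
    fc_in <- arch$n_streams * arch$stream_units
    widths <- c(arch$fc_widths, arch$n_classes)
    fc <- list()
    for (i in seq_along(widths)) {
      fc[[i]] <- list(W = .init_mat(widths[i], fc_in, fc_in),
                      b = numeric(widths[i]))
      fc_in <- widths[i]
    }
    structure(list(arch = arch, streams = streams, fc = fc,
                   seed = as.integer(seed), classes = NULL),
              class = "stream_net")
  })
}

#' @export
print.stream_net <- function(x, ...) {
  cat(sprintf("<stream_net %d streams, %d conv layers/stream, %d classes, %s params>\n",
              x$arch$n_streams, length(x$arch$conv_layers), x$arch$n_classes,
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model a `stream_net`.
#' @return integer parameter count.
#' @export
count_params <- function(model) {
  n <- 0
  for (st in model$streams) for (ly in st) n <- n + length(ly$W) + length(ly$b)
  for (f in model$fc) n <- n + length(f$W) + length(f$b)
  n
}

.layer_index <- function(model, layer_name) {
  m <- regmatches(layer_name, regexec("^conv([0-9]+)$", layer_name))[[1]]
  .assert(length(m) == 2, sprintf("unknown layer '%s'", layer_name))
  l <- as.integer(m[2])
  .assert(l >= 1 && l <= length(model$arch$conv_layers),
          sprintf("layer '%s' does not exist (model has conv1..conv%d)",
                  layer_name, length(model$arch$conv_layers)))
  l
}

.check_stream <- function(model, stream_id) {
  .assert(length(stream_id) == 1 && stream_id >= 1 &&
            stream_id <= model$arch$n_streams,
          sprintf("stream %s does not exist (model has %d streams)",
                  stream_id, model$arch$n_streams))
  as.integer(stream_id)
}

#' Extract convolution kernels from a layer
#'
#' @param model a `stream_net` (or deletion view; weights are shared).
#' @param layer_name layer name, `"conv1"` ... `"convL"`.
#' @param stream_id stream number.
#' @return list of [filter_kernel()] in filter-index order.
#' @export
get_kernels <- function(model, layer_name = "conv1", stream_id = 1) {
  net <- .resolve_net(model)
  model <- net$model
  l <- .layer_index(model, layer_name)
  s <- .check_stream(model, stream_id)
  W <- model$streams[[s]][[l]]$W
  lapply(seq_len(dim(W)[4]), function(i) {
    filter_kernel(W[, , , i, drop = FALSE][, , , 1],
                  layer = layer_name, stream = s, index = i)
  })
}

#' Save / load a model checkpoint
#'
#' Checkpoints round-trip weights, architecture and training provenance
#' bit-exactly.
#'
#' @param model a `stream_net`.
#' @param path file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Evaluate a model with one stream's output deleted
#'
#' Returns a lightweight view: during forward passes the deleted stream's
#' contribution to the concatenated feature vector (its last max-pool
#' output) is replaced elementwise by 0 (`"zero"` mode) or by the scalar
#' mean of the values it replaces, computed over all units and images of the
#' current batch (`"mean"` mode — preserves overall activity level while
#' destroying the variance across units). Weights are untouched and the
#' original model is unaffected; views compose, so deleting several streams
#' sequentially is possible.
#'
#' @param model a `stream_net` or an existing deletion view.
#' @param stream_id stream to delete.
#' @param mode `"zero"` or `"mean"`.
#' @return object of class `stream_net_view`.
#' @export
with_stream_deleted <- function(model, stream_id, mode = c("zero", "mean")) {
  mode <- match.arg(mode)
  net <- .resolve_net(model)
  s <- .check_stream(net$model, stream_id)
  structure(list(model = net$model,
                 deleted = c(net$deleted, list(list(stream = s, mode = mode)))),
            class = "stream_net_view")
}

# Normalize a model-or-view into list(model, deleted).
.resolve_net <- function(x) {
  if (inherits(x, "stream_net_view")) {
    list(model = x$model, deleted = x$deleted)
  } else if (inherits(x, "stream_net")) {
    list(model = x, deleted = list())
  } else {
    stop("expected a stream_net or stream_net_view", call. = FALSE)
  }
}
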
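# Most effective stimulus (MES) synthesis: gradient ascent on the input
# image maximizing the spatial mean of one filter's post-ReLU activation
# map. Filters in layers beyond the first have many input channels and
# cannot be visualized directly; their MES makes their tuning measurable
# with the same colour/spatial-frequency metrics used for first-layer
# kernels.

#' Synthesize the most effective stimulus for a filter
#'
#' Iterative gradient ascent from a random RGB image. Each step normalizes
#' the input gradient to unit norm, moves by `step_size` (default 0.2 pixel-units), clips pixels to
#' \[0, 1\], and is accepted only if the objective (the mean of the filter's
#' activation map) does not decrease; a rejected step halves the step size
#' instead, so the objective trace over accepted steps is non-decreasing.
#'
#' @param model a trained `stream_net`.
#' @param layer_name conv layer of the target filter.
#' @param stream_id stream of the target filter.
#' @param filter_index filter index within the layer.
#' @param n_steps ascent iterations (default 256).
#' @param step_size initial ascent step in pixel units (default 0.2; large
#'   enough that the default step budget can reach full-contrast patterns
#'   from the mid-gray start, with rejected steps shrinking it near optima).
#' @param blur_every apply a mild 3x3 binomial blur every this many steps to
#'   suppress pixel-level artifacts; 0 (default) disables it, keeping the
#'   procedure strictly deterministic in `seed`.
#' @param seed seed for the random initial image (uniform per-pixel RGB in
#'   `init_range` around mid-gray).
#' @param init_range range of the random initial image.
#' @return object of class `mes`: `image` ((H, W, 3) array in \[0,1\]),
#'   `final_objective`, `initial_objective`, `n_steps`, `seed`,
#'   `dead_filter`, `trace`, filter provenance, and the MES metrics
#'   `color_index` and `preferred_sf` (cycles/image).
#' @export
synthesize_mes <- function(model, layer_name, stream_id, filter_index,
                           n_steps = 256, step_size = 0.2, blur_every = 0,
                           seed = 1, init_range = c(0.4, 0.6)) {
  net <- .resolve_net(model)
  model <- net$model
  l <- .layer_index(model, layer_name)
  s <- .check_stream(model, stream_id)
  nf <- model$arch$conv_layers[[l]]$n_filters
  .assert(filter_index >= 1 && filter_index <= nf,
          sprintf("filter %d does not exist (%s has %d filters)",
                  filter_index, layer_name, nf))
  n <- model$arch$input_size
  x <- .with_seed(seed, array(stats::runif(n * n * 3, init_range[1],
                                           init_range[2]),
                              dim = c(n, n, 3, 1)))

  objective_and_grad <- function(x) {
    fw <- .stream_forward_cache_upto(model, s, x, l)
    map <- fw$out[, , filter_index, 1]
    obj <- mean(map)
    dmap <- array(0, dim = dim(fw$out))
    dmap[, , filter_index, 1] <- 1 / length(map)
    dmap <- dmap * fw$mask_top
    dx <- .partial_stream_backward(model, s, fw$caches, dmap, l)
    list(obj = obj, grad = dx)
  }

  og <- objective_and_grad(x)
  initial_objective <- og$obj
  if (sqrt(sum(og$grad^2)) == 0) {
    img <- x[, , , 1]
    return(structure(list(image = img, final_objective = og$obj,
                          initial_objective = initial_objective,
                          n_steps = 0L, seed = seed, dead_filter = TRUE,
                          trace = og$obj, layer = layer_name, stream = s,
                          filter_index = filter_index,
                          color_index = mes_color_index(img),
                          preferred_sf = mes_preferred_sf(img)),
                     class = "mes"))
  }
  trace <- numeric(n_steps + 1)
  trace[1] <- og$obj
  step <- step_size
  for (it in seq_len(n_steps)) {
    g <- og$grad
    gn <- sqrt(sum(g^2))
    cand <- x
    if (gn > 0) cand <- pmin(pmax(x + step * g / gn, 0), 1)
    if (blur_every > 0 && it %% blur_every == 0) cand <- .blur3(cand)
    cand_og <- objective_and_grad(cand)
    if (cand_og$obj >= og$obj) {
      x <- cand
      og <- cand_og
      step <- min(step * 1.2, step_size)   # regrow after successes
    } else {
      step <- step / 2
    }
    trace[it + 1] <- og$obj
  }
  img <- x[, , , 1]
  structure(list(image = img, final_objective = og$obj,
                 initial_objective = initial_objective,
                 n_steps = as.integer(n_steps), seed = seed,
                 dead_filter = FALSE, trace = trace, layer = layer_name,
                 stream = s, filter_index = filter_index,
                 color_index = mes_color_index(img),
                 preferred_sf = mes_preferred_sf(img)),
            class = "mes")
}

#' @export
print.mes <- function(x, ...) {
  cat(sprintf("<mes %s stream %d filter %d  objective %.4g%s  color %.3f  sf %d>\n",
              x$layer, x$stream, x$filter_index, x$final_objective,
              if (x$dead_filter) " (dead filter)" else "",
              x$color_index, x$preferred_sf))
  invisible(x)
}

# Forward one stream keeping caches, stopping at layer `upto`; also returns
# the ReLU mask at the top layer (the objective is post-ReLU).
.stream_forward_cache_upto <- function(model, s, x, upto) {
  layers <- model$streams[[s]]
  caches <- vector("list", upto)
  a <- x
  for (l in seq_len(upto)) {
    ly <- layers[[l]]
    z <- .conv2d_forward_cpp(a, ly$W, ly$b, ly$stride, ly$padding)
    act <- .relu(z)
    if (l == upto) {
      caches[[l]] <- list(x_in = a, mask = z > 0, act_dim = dim(act),
                          pool_idx = NULL)
      return(list(out = act, caches = caches, mask_top = z > 0))
    }
    pooled <- act
    pool_idx <- NULL
    if (ly$pool_after) {
      mp <- .maxpool_forward_cpp(act, ly$pool_size, ly$pool_stride)
      pooled <- mp$out
      pool_idx <- mp$idx
    }
    caches[[l]] <- list(x_in = a, mask = z > 0, act_dim = dim(act),
                        pool_idx = pool_idx)
    a <- pooled
  }
}

# Backward from a gradient at layer `upto`'s (already ReLU-gated) pre-pool
# map down to the input image.
.partial_stream_backward <- function(model, s, caches, g, upto) {
  layers <- model$streams[[s]]
  for (l in rev(seq_len(upto))) {
    ly <- layers[[l]]
    cc <- caches[[l]]
    if (l < upto) {
      if (ly$pool_after) {
        g <- .maxpool_backward_cpp(cc$pool_idx, g, as.integer(cc$act_dim))
      }
      g <- g * cc$mask
    }
    bw <- .conv2d_backward_cpp(cc$x_in, ly$W, g, ly$stride, ly$padding)
    g <- bw$dx
  }
  g
}

# Separable 3x3 binomial ([1,2,1]/4) blur of an (H, W, 3, 1) array.
.blur3 <- function(x) {
  sm <- function(m) {
    n <- nrow(m)
    up <- m[c(1, 1:(n - 1)), ]; dn <- m[c(2:n, n), ]
    m <- (up + 2 * m + dn) / 4
    le <- m[, c(1, 1:(n - 1))]; ri <- m[, c(2:n, n)]
    (le + 2 * m + ri) / 4
  }
  for (c in 1:3) x[, , c, 1] <- sm(x[, , c, 1])
  x
}

#' Colour index of an image
#'
#' Same construction as the kernel colour index but over pixel values: the
#' smallest pairwise correlation among the R, G, B channels mapped through
#' `r_min * (-0.5) + 0.5`.
#'
#' @param image (H, W, 3) array.
#' @return colour index in \[0, 1\], or `NA` for a constant image (the
#'   correlations are undefined with no structure at all).
#' @export
mes_color_index <- function(image) {
  .assert(is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3,
          "image must be an (H, W, 3) array")
  ch <- matrix(image, ncol = 3)
  sds <- apply(ch, 2, stats::sd)
  if (all(sds == 0)) return(NA_real_)   # constant image: undefined
  .rmin_color_index(ch)$color_index
}

#' Preferred spatial frequency of an image
#'
#' Radial-annulus DFT amplitude summation (the same spectral geometry as
#' the kernel metric) on the image's preferred colour channel; returns the
#' annulus of maximal amplitude in 0..floor(W/2) cycles/image. The channel
#' mean is removed before the transform: an image's mean level is an
#' arbitrary offset of the \[0, 1\] pixel encoding, and leaving it in would
#' let the DC annulus dominate every stimulus regardless of its structure
#' (kernels, whose weights are signed and whose DC response is a genuine
#' tuning property, keep their DC annulus in [preferred_sf()]). A
#' structureless (uniform) image reports 0 (DC).
#'
#' @param image (H, W, 3) array (square).
#' @return integer cycles/image.
#' @export
mes_preferred_sf <- function(image) {
  .assert(is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3,
          "image must be an (H, W, 3) array")
  .assert(dim(image)[1] == dim(image)[2], "image must be square")
  amps_by_chan <- vapply(1:3, function(c) .total_amplitude_nodc(image[, , c]),
                         numeric(1))
  chan <- which.max(amps_by_chan)
  m <- image[, , chan]
  amps <- sf_annulus_amplitudes(m - mean(m))
  as.integer(names(amps)[which.max(amps)])
}

#' MES summary for a set of filters
#'
#' @param model a trained `stream_net`.
#' @param layer_name conv layer.
#' @param stream_id stream.
#' @param filter_indices filters to synthesize (default all in the layer).
#' @param ... passed to [synthesize_mes()].
#' @return data.frame with one row per filter: `final_objective`,
#'   `dead_filter`, `color_index`, `preferred_sf`.
#' @export
mes_summary <- function(model, layer_name, stream_id, filter_indices = NULL,
                        ...) {
  net <- .resolve_net(model)
  l <- .layer_index(net$model, layer_name)
  if (is.null(filter_indices)) {
    filter_indices <- seq_len(net$model$arch$conv_layers[[l]]$n_filters)
  }
  rows <- lapply(filter_indices, function(fi) {
    m <- synthesize_mes(net$model, layer_name, stream_id, fi, ...)
    data.frame(layer = layer_name, stream = stream_id, filter_index = fi,
               final_objective = m$final_objective,
               dead_filter = m$dead_filter,
               color_index = m$color_index,
               preferred_sf = m$preferred_sf)
  })
  do.call(rbind, rows)
}
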
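# Synthetic filter kernels with known ground-truth tuning. These are the
# validation fixtures for the spectral tuning metrics: a Gabor's orientation
# and spatial frequency, a colour blob's hue, and a flat kernel's absence of
# structure are all recoverable analytically.

#' Specification of a synthetic convolution kernel
#'
#' @param kind one of `"gabor"`, `"color_blob"`, `"flat"`,
#'   `"grayscale_noise"`, `"color_noise"`.
#' @param size kernel side in pixels; must be odd (default 11).
#' @param orientation_deg Gabor orientation in degrees, in \[0, 180).
#'   Orientation is the direction of the frequency vector, i.e. the axis
#'   along which the sinusoid varies (perpendicular to the stripes).
#' @param sf_cycles integer spatial frequency in cycles per filter width.
#' @param hue length-3 RGB channel gains; negative gains give
#'   colour-opponent kernels (e.g. `c(1, -1, 0)` for red-green opponency).
#' @param seed integer seed (used by the noise kinds).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(kind, size = 11, orientation_deg = 0, sf_cycles = 2,
                        hue = c(1, 1, 1), seed = 1) {
  kinds <- c("gabor", "color_blob", "flat", "grayscale_noise", "color_noise")
  .assert(is.character(kind) && kind %in% kinds,
          paste0("kind must be one of: ", paste(kinds, collapse = ", ")))
  .assert(size >= 3 && size %% 2 == 1, "size must be an odd integer >= 3")
  .assert(orientation_deg >= 0 && orientation_deg < 180,
          "orientation_deg must lie in [0, 180)")
  .assert(sf_cycles >= 0 && sf_cycles == round(sf_cycles),
          "sf_cycles must be a nonnegative integer")
  .assert(length(hue) == 3 && all(is.finite(hue)),
          "hue must be 3 finite channel gains")
  structure(list(kind = kind, size = as.integer(size),
                 orientation_deg = orientation_deg,
                 sf_cycles = as.integer(sf_cycles),
                 hue = as.numeric(hue), seed = as.integer(seed)),
            class = "filter_spec")
}

#' Construct a filter kernel object
#'
#' A `filter_kernel` carries one convolution kernel's weights as a
#' (k, k, channels) array plus layer/stream/index provenance.
#'
#' @param weights numeric (k, k, channels) array.
#' @param layer layer name, e.g. `"conv1"`.
#' @param stream stream id (integer or `NA`).
#' @param index filter index within the layer (integer or `NA`).
#' @return object of class `filter_kernel`.
#' @export
filter_kernel <- function(weights, layer = "synthetic", stream = NA_integer_,
                          index = NA_integer_) {
  .assert(is.array(weights) && length(dim(weights)) == 3,
          "weights must be a 3-D (k, k, channels) array")
  structure(list(weights = weights, layer = layer,
                 stream = stream, index = index),
            class = "filter_kernel")
}

#' @export
print.filter_kernel <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("<filter_kernel %dx%dx%d  layer=%s stream=%s index=%s>\n",
              d[1], d[2], d[3], x$layer, x$stream, x$index))
  invisible(x)
}

#' Generate a synthetic kernel from its specification
#'
#' Kinds: `gabor` is a sinusoid at `orientation_deg` and `sf_cycles`
#' (cycles per filter width) under a Gaussian envelope, mean-centred per
#' channel and scaled by the `hue` gains; `color_blob` is a low-frequency
#' Gaussian bump with per-channel gains from `hue` (DC-dominated, so its
#' preferred spatial frequency is 0); `flat` is identically zero;
#' `grayscale_noise` replicates one Gaussian-noise channel three times;
#' `color_noise` draws the three channels independently.
#'
#' @param spec a [filter_spec()].
#' @return a [filter_kernel()].
#' @export
make_filter <- function(spec) {
  .assert(inherits(spec, "filter_spec"), "spec must be a filter_spec")
  k <- spec$size
  centre <- (k + 1) / 2
  u <- matrix((seq_len(k) - centre) / k, k, k, byrow = TRUE)  # x along cols
  v <- matrix((seq_len(k) - centre) / k, k, k)                # y along rows
  w <- array(0, dim = c(k, k, 3))
  if (spec$kind == "gabor") {
    th <- spec$orientation_deg * pi / 180
    carrier <- cos(2 * pi * spec$sf_cycles * (u * cos(th) + v * sin(th)))
    envelope <- exp(-(u^2 + v^2) / (2 * 0.25^2))
    g <- carrier * envelope
    g <- g - mean(g)                       # exact zero mean per channel
    for (c in 1:3) w[, , c] <- spec$hue[c] * g
  } else if (spec$kind == "color_blob") {
    blob <- exp(-(u^2 + v^2) / (2 * 0.25^2))
    for (c in 1:3) w[, , c] <- spec$hue[c] * blob
  } else if (spec$kind == "flat") {
    # zeros: zero variance in every channel
  } else if (spec$kind == "grayscale_noise") {
    g <- .with_seed(spec$seed, matrix(stats::rnorm(k * k, sd = 0.1), k, k))
    for (c in 1:3) w[, , c] <- spec$hue[c] * g
  } else if (spec$kind == "color_noise") {
    w[] <- .with_seed(spec$seed, stats::rnorm(3 * k * k, sd = 0.1))
    for (c in 1:3) w[, , c] <- spec$hue[c] * w[, , c]
  }
  filter_kernel(w, layer = "synthetic")
}

#' Gabor filter bank with ground-truth tuning
#'
#' Convenience generator crossing orientations and spatial frequencies,
#' used to validate that the tuning metrics recover known parameters.
#'
#' @param orientations vector of orientations in degrees.
#' @param sfs vector of integer spatial frequencies (cycles/filter).
#' @param size kernel side (odd).
#' @param hue RGB gains applied to every kernel.
#' @return list with `kernels` (list of [filter_kernel()]) and `truth`
#'   (data.frame of generating orientation and sf per kernel).
#' @export
gabor_bank <- function(orientations = seq(0, 150, by = 30), sfs = NULL,
                       size = 11, hue = c(1, 1, 1)) {
  if (is.null(sfs)) sfs <- seq_len(size %/% 2)
  grid <- expand.grid(orientation = orientations, sf = sfs)
  kernels <- lapply(seq_len(nrow(grid)), function(i) {
    kk <- make_filter(filter_spec("gabor", size = size,
                                  orientation_deg = grid$orientation[i],
                                  sf_cycles = grid$sf[i], hue = hue))
    kk$index <- i
    kk
  })
  list(kernels = kernels, truth = grid)
}
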
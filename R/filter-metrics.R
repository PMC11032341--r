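# Per-filter tuning metrics for first-layer (RGB-facing) kernels: flatness
# screening, colour index from pairwise channel correlations, orientation
# index and preferred spatial frequency from the 2-D DFT amplitude spectrum
# of the preferred colour channel.

.kernel_channels <- function(kernel) {
  w <- kernel$weights
  matrix(w, ncol = dim(w)[3])
}

#' Flatness screen for a kernel
#'
#' A kernel is flat when every channel's weight standard deviation is at
#' most `tol` times a reference scale. Flat kernels developed no structure
#' during training and are excluded from the index analyses.
#'
#' @param kernel a [filter_kernel()].
#' @param tol relative tolerance (default 1e-6).
#' @param scale reference scale; defaults to the kernel's largest absolute
#'   weight. [analyze_filter_bank()] passes the bank-wide maximum channel SD
#'   so the screen is consistent across a bank.
#' @return logical.
#' @export
flatness_test <- function(kernel, tol = 1e-6, scale = NULL) {
  ch <- .kernel_channels(kernel)
  sds <- apply(ch, 2, stats::sd)
  if (is.null(scale)) scale <- max(abs(ch))
  if (scale == 0) return(TRUE)
  all(sds <= tol * scale)
}

#' Colour index of a kernel
#'
#' Pairwise product-moment correlations of the flattened weights between the
#' R-G, R-B and G-B channel pairs; the smallest (`r_min`) gives
#' `color_index = r_min * (-0.5) + 0.5`, in \[0, 1\] (0 = achromatic,
#' 1 = strongly chromatic). When one or two channels are flat the
#' correlation is undefined but the filter is unambiguously colour
#' selective, so the index is set to 1.
#'
#' @param kernel a non-flat [filter_kernel()].
#' @return list with `color_index` and `r_min` (`NA` when pinned to 1).
#' @export
color_index <- function(kernel) {
  .assert(!flatness_test(kernel),
          "kernel is flat; colour index is undefined (screen with flatness_test)")
  .rmin_color_index(.kernel_channels(kernel))
}

#' Preferred colour channel of a kernel
#'
#' The channel with the largest total DFT amplitude (DC excluded,
#' non-redundant half-plane). Ties break in fixed R > G > B order.
#'
#' @param kernel a non-flat [filter_kernel()].
#' @return `"R"`, `"G"` or `"B"`.
#' @export
preferred_channel <- function(kernel) {
  w <- kernel$weights
  amps <- vapply(seq_len(dim(w)[3]),
                 function(c) .total_amplitude_nodc(w[, , c]), numeric(1))
  c("R", "G", "B")[which.max(amps)]   # which.max keeps the first of ties
}

#' Orientation index of a kernel
#'
#' The DFT amplitude of the preferred colour channel is summed into six
#' 30-degree orientation bins (±15° around centres 0, 30, ..., 150°; DC
#' excluded). `Amplitude_p` is the largest bin, `Amplitude_o` the bin
#' orthogonal to it, and the index is
#' `(Amplitude_p - Amplitude_o) / (Amplitude_p + Amplitude_o)`, in \[0, 1\]
#' because the preferred bin is the maximum.
#'
#' @param kernel a non-flat [filter_kernel()].
#' @return list with `orientation_index`, `preferred_orientation_deg`,
#'   `bin_centers_deg` and `bin_amplitudes`.
#' @export
orientation_index <- function(kernel) {
  chan <- match(preferred_channel(kernel), c("R", "G", "B"))
  bins <- orientation_bin_amplitudes(kernel$weights[, , chan])
  .assert(sum(bins) > 0,
          "zero spectral amplitude; kernel should have been screened as flat")
  centers <- seq(0, 150, by = 30)
  p <- which.max(bins)
  o <- which(centers == (centers[p] + 90) %% 180)
  list(orientation_index = (bins[[p]] - bins[[o]]) / (bins[[p]] + bins[[o]]),
       preferred_orientation_deg = centers[p],
       bin_centers_deg = centers, bin_amplitudes = unname(bins))
}

#' Preferred spatial frequency of a kernel
#'
#' DFT amplitude of the preferred colour channel summed along circular
#' annuli at integer radial frequencies 0 (DC) to floor(k/2) cycles/filter;
#' the preferred SF is the annulus with maximal amplitude (lowest frequency
#' wins ties).
#'
#' @param kernel a non-flat [filter_kernel()].
#' @return list with `preferred_sf` (integer cycles/filter) and
#'   `sf_amplitudes` (named by frequency 0..floor(k/2)).
#' @export
preferred_sf <- function(kernel) {
  chan <- match(preferred_channel(kernel), c("R", "G", "B"))
  amps <- sf_annulus_amplitudes(kernel$weights[, , chan])
  list(preferred_sf = as.integer(names(amps)[which.max(amps)]),
       sf_amplitudes = amps)
}

#' Tuning analysis of a filter bank
#'
#' Applies the flatness screen and the three tuning metrics to every kernel.
#' The flatness scale is the bank-wide maximum channel SD, so "flat" means
#' flat relative to the structure the bank developed. Flat filters keep
#' their row but carry `NA` index values.
#'
#' @param kernels list of [filter_kernel()] (e.g. from [get_kernels()]).
#' @param tol relative flatness tolerance.
#' @return data.frame with one row per filter: provenance, `is_flat`,
#'   `r_min`, `color_index`, `preferred_channel`,
#'   `preferred_orientation_deg`, `orientation_index`, `preferred_sf`.
#' @export
analyze_filter_bank <- function(kernels, tol = 1e-6) {
  .assert(length(kernels) >= 1, "empty kernel list")
  bank_scale <- max(vapply(kernels, function(k) {
    max(apply(.kernel_channels(k), 2, stats::sd))
  }, numeric(1)))
  rows <- lapply(seq_along(kernels), function(i) {
    k <- kernels[[i]]
    base <- data.frame(layer = k$layer, stream = k$stream,
                       filter_index = if (is.na(k$index)) i else k$index,
                       is_flat = flatness_test(k, tol, scale = bank_scale),
                       r_min = NA_real_, color_index = NA_real_,
                       preferred_channel = NA_character_,
                       preferred_orientation_deg = NA_real_,
                       orientation_index = NA_real_,
                       preferred_sf = NA_integer_,
                       stringsAsFactors = FALSE)
    if (!base$is_flat) {
      ci <- color_index(k)
      oi <- orientation_index(k)
      sf <- preferred_sf(k)
      base$r_min <- ci$r_min
      base$color_index <- ci$color_index
      base$preferred_channel <- preferred_channel(k)
      base$preferred_orientation_deg <- oi$preferred_orientation_deg
      base$orientation_index <- oi$orientation_index
      base$preferred_sf <- sf$preferred_sf
    }
    base
  })
  do.call(rbind, rows)
}
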
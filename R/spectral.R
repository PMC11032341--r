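# Shared 2-D DFT machinery used for both convolution kernels (cycles/filter)
# and whole images (cycles/image). One geometry serves both: the tuning
# metrics must agree between the kernel-sized and image-sized code paths.

# Signed DFT frequency axis for length n (R fft ordering).
.fft_freqs <- function(n) {
  c(0:(n %/% 2), seq_len(n - n %/% 2 - 1) - (n - n %/% 2))
}

#' Spectral geometry of an n x n DFT grid
#'
#' Precomputes, for every coefficient of an `n` x `n` 2-D DFT, its signed
#' frequency vector, orientation (degrees in \[0, 180)), radial frequency,
#' and a conjugate-symmetry weight. Real inputs have conjugate-symmetric
#' spectra, so each conjugate pair must be counted once: pair members get
#' weight 1/2 each and self-conjugate coefficients (DC, and Nyquist cells
#' on even grids) weight 1. On odd grids this equals a half-plane
#' traversal; on even grids it also splits Nyquist-aliased pairs — whose
#' two members sit at *reflected* orientations and are genuinely ambiguous
#' — evenly between their bins.
#'
#' @param n grid side in pixels.
#' @return list with matrices `fx`, `fy` (column/row frequency),
#'   `angle_deg`, `radius`, `weight`, and logical `dc` (the DC cell).
#' @keywords internal
.spectral_geometry <- function(n) {
  f <- .fft_freqs(n)
  fy <- matrix(f, n, n)        # row frequency varies along rows
  fx <- matrix(f, n, n, byrow = TRUE)
  angle <- (atan2(fy, fx) * 180 / pi) %% 180
  radius <- sqrt(fx^2 + fy^2)
  # conjugate mirror of grid cell (i, j) is (-i mod n, -j mod n) (0-based)
  i0 <- matrix(0:(n - 1), n, n)
  j0 <- matrix(0:(n - 1), n, n, byrow = TRUE)
  self_conj <- (((n - i0) %% n) == i0) & (((n - j0) %% n) == j0)
  weight <- ifelse(self_conj, 1, 0.5)
  dc <- fx == 0 & fy == 0
  list(n = n, fx = fx, fy = fy, angle_deg = angle, radius = radius,
       weight = weight, dc = dc)
}

# Memoized geometry lookup (sizes recur constantly across a filter bank).
.geom_cache <- new.env(parent = emptyenv())
.geometry <- function(n) {
  key <- as.character(n)
  if (is.null(.geom_cache[[key]])) .geom_cache[[key]] <- .spectral_geometry(n)
  .geom_cache[[key]]
}

# 2-D DFT amplitude spectrum of a square matrix.
.amplitude_spectrum <- function(m) Mod(stats::fft(m))

#' Orientation-bin amplitudes of a square channel
#'
#' Sums DFT amplitude into six 30-degree-wide orientation bins centred at
#' 0, 30, ..., 150 degrees (half-open \[centre-15, centre+15) so the bins
#' partition \[0, 180)). Conjugate pairs are counted once (half weight per
#' member) and DC is excluded (the orientation of the zero frequency
#' vector is undefined).
#'
#' @param m numeric square matrix (one colour channel of a kernel or image).
#' @return named numeric vector of six bin amplitudes; names are bin centres.
#' @export
orientation_bin_amplitudes <- function(m) {
  .assert(is.matrix(m) && nrow(m) == ncol(m), "m must be a square matrix")
  g <- .geometry(nrow(m))
  amp <- .amplitude_spectrum(m)
  keep <- !g$dc
  bin <- (floor(((g$angle_deg[keep] + 15) %% 180) / 30) %% 6) + 1L
  out <- numeric(6)
  agg <- tapply(amp[keep] * g$weight[keep], bin, sum)
  out[as.integer(names(agg))] <- agg
  names(out) <- as.character(seq(0, 150, by = 30))
  out
}

#' Radial spatial-frequency amplitudes of a square channel
#'
#' Sums DFT amplitude along circular annuli at integer radial frequencies
#' 0 (DC) to floor(n/2) cycles per side. Each coefficient is assigned to
#' the annulus nearest its radial frequency (coefficients beyond the last
#' annulus fold into it); conjugate pairs are counted once.
#'
#' @param m numeric square matrix.
#' @return numeric vector of length floor(n/2)+1, named "0", "1", ...
#' @export
sf_annulus_amplitudes <- function(m) {
  .assert(is.matrix(m) && nrow(m) == ncol(m), "m must be a square matrix")
  n <- nrow(m)
  g <- .geometry(n)
  amp <- .amplitude_spectrum(m)
  fmax <- n %/% 2
  ann <- pmin(round(g$radius), fmax)
  out <- numeric(fmax + 1)
  agg <- tapply(amp * g$weight, ann, sum)
  out[as.integer(names(agg)) + 1L] <- agg
  names(out) <- as.character(0:fmax)
  out
}

# Total spectral amplitude excluding DC (conjugate pairs counted once),
# used to pick the preferred colour channel of a kernel or image.
.total_amplitude_nodc <- function(m) {
  g <- .geometry(nrow(m))
  amp <- .amplitude_spectrum(m)
  sum(amp[!g$dc] * g$weight[!g$dc])
}

# Smallest pairwise channel correlation -> colour index, shared by the
# kernel-based and image-based colour metrics. `channels` is a numeric
# matrix with one column per colour channel (R, G, B).
# Returns list(color_index, r_min); r_min is NA when some (not all)
# channels are constant, in which case the index is pinned to 1.
.rmin_color_index <- function(channels) {
  sds <- apply(channels, 2, stats::sd)
  if (all(sds == 0)) {
    stop("all channels are constant; colour index undefined", call. = FALSE)
  }
  if (any(sds == 0)) {
    # a flat channel against structured channels is unambiguous colour
    # selectivity; the correlation is undefined so the index is set to 1
    return(list(color_index = 1, r_min = NA_real_))
  }
  r <- c(stats::cor(channels[, 1], channels[, 2]),
         stats::cor(channels[, 1], channels[, 3]),
         stats::cor(channels[, 2], channels[, 3]))
  r_min <- min(r)
  list(color_index = r_min * (-0.5) + 0.5, r_min = r_min)
}
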
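# Independent oracles, deliberately written with different machinery than
# the package implementation: explicit per-coefficient loops, pair counting,
# and sort-based ranking.

# Signed frequency of 0-based DFT index i on an n-grid.
oracle_freq <- function(i, n) if (i <= n %/% 2) i else i - n

# Brute-force orientation-bin amplitudes: loop over every DFT coefficient,
# classify its angle, and weight self-conjugate coefficients once and
# conjugate pairs half each (summing the full plane this way equals a
# single traversal of the non-redundant half-plane).
oracle_orientation_bins <- function(m) {
  n <- nrow(m)
  A <- Mod(stats::fft(m))
  bins <- numeric(6)
  for (i in 0:(n - 1)) {
    for (j in 0:(n - 1)) {
      fy <- oracle_freq(i, n); fx <- oracle_freq(j, n)
      if (fx == 0 && fy == 0) next                      # DC excluded
      self_conj <- ((-i) %% n) == i && ((-j) %% n) == j
      wgt <- if (self_conj) 1 else 0.5
      ang <- (atan2(fy, fx) * 180 / pi) %% 180
      b <- (floor(((ang + 15) %% 180) / 30) %% 6) + 1
      bins[b] <- bins[b] + wgt * A[i + 1, j + 1]
    }
  }
  bins
}

# Brute-force SF-annulus amplitudes with the same explicit traversal.
oracle_sf_annuli <- function(m) {
  n <- nrow(m)
  A <- Mod(stats::fft(m))
  fmax <- n %/% 2
  ann <- numeric(fmax + 1)
  for (i in 0:(n - 1)) {
    for (j in 0:(n - 1)) {
      fy <- oracle_freq(i, n); fx <- oracle_freq(j, n)
      self_conj <- ((-i) %% n) == i && ((-j) %% n) == j
      wgt <- if (self_conj) 1 else 0.5
      r <- min(round(sqrt(fx^2 + fy^2)), fmax)
      ann[r + 1] <- ann[r + 1] + wgt * A[i + 1, j + 1]
    }
  }
  ann
}

# Pair-counting AUC: P(delta_A > delta_B) with ties counted one half.
oracle_pair_auc <- function(delta, is_a) {
  da <- delta[is_a]; db <- delta[!is_a]
  tot <- 0
  for (a in da) for (b in db) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(da) * length(db))
}

# Sort-and-average-ties rank normalization of a distance matrix's lower
# triangle onto [0, 1].
oracle_rank_normalize <- function(raw) {
  v <- raw[lower.tri(raw)]
  np <- length(v)
  rk <- numeric(np)
  for (i in seq_len(np)) {
    rk[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }
  out <- matrix(0, nrow(raw), ncol(raw))
  out[lower.tri(out)] <- (rk - 1) / (np - 1)
  out + t(out)
}

# Pixel-space nearest-centroid classifier accuracy (leave-set-out: train
# centroids on the train split, score the eval split). `transform` maps an
# (H, W, 3) image to the feature vector the oracle is restricted to.
oracle_nearest_centroid <- function(train_x, train_y, eval_x, eval_y,
                                    transform) {
  feats <- function(x) {
    t(vapply(seq_len(dim(x)[4]), function(i) transform(x[, , , i]),
             numeric(length(transform(x[, , , 1])))))
  }
  ftr <- feats(train_x); fev <- feats(eval_x)
  ids <- sort(unique(train_y))
  cents <- t(vapply(ids, function(id) colMeans(ftr[train_y == id, , drop = FALSE]),
                    numeric(ncol(ftr))))
  pred <- ids[apply(fev, 1, function(v) {
    which.min(colSums((t(cents) - v)^2))
  })]
  mean(pred == eval_y)
}

# Hue-channel feature: mean-removed chromatic content (per-pixel channel
# deviations from the pixel's luminance), discarding spatial structure by
# averaging over pixels.
hue_feature <- function(img) {
  lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  c(mean(img[, , 1] - lum), mean(img[, , 2] - lum), mean(img[, , 3] - lum))
}

# Contour feature: high-pass grayscale image (luminance minus a 3x3 local
# mean), which keeps edges and discards hue.
contour_feature <- function(img) {
  lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  n <- nrow(lum)
  sm <- (lum[c(1, 1:(n - 1)), ] + lum + lum[c(2:n, n), ]) / 3
  sm <- (sm[, c(1, 1:(n - 1))] + sm + sm[, c(2:n, n)]) / 3
  as.numeric(lum - sm)
}
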
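test_that("RDM matches a hand-ranked oracle on small stimulus sets", {
  set.seed(14)
  acts <- matrix(rnorm(4 * 12), 4, 12)
  r <- compute_rdm(acts)
  raw <- 1 - cor(t(acts))
  expect_equal(r$values, oracle_rank_normalize(raw), tolerance = 1e-12)
  expect_identical(diag(r$values), rep(0, 4))
  expect_identical(r$values, t(r$values))
  expect_true(all(r$values[lower.tri(r$values)] >= 0 &
                    r$values[lower.tri(r$values)] <= 1))

  # a duplicated stimulus pair attains the minimum normalized rank
  acts2 <- rbind(acts, acts[1, ])
  r2 <- compute_rdm(acts2)
  expect_identical(r2$values[5, 1], 0)
})

test_that("rank normalization is exactly invariant to monotone distance maps", {
  set.seed(15)
  acts <- matrix(rnorm(8 * 10), 8, 10)
  r <- compute_rdm(acts, distance = "euclidean")
  raw <- as.matrix(dist(acts))
  for (f in list(function(d) d^2, function(d) log1p(d),
                 function(d) 10 * d + 3)) {
    expect_identical(r$values, oracle_rank_normalize(f(raw)))
  }
  # scaling activations scales euclidean distances monotonically
  r2 <- compute_rdm(3 * acts, distance = "euclidean")
  expect_identical(r$values, r2$values)
})

test_that("RDM is invariant to filter order and equivariant to stimulus order", {
  set.seed(16)
  acts <- array(rnorm(6 * 5 * 3 * 3), c(6, 5, 3, 3))
  r <- compute_rdm(acts)
  rperm <- compute_rdm(acts[, sample(5), , , drop = FALSE])
  expect_equal(r$values, rperm$values, tolerance = 1e-12)
  sperm <- c(3, 1, 6, 2, 5, 4)
  rs <- compute_rdm(acts[sperm, , , , drop = FALSE])
  expect_equal(rs$values, r$values[sperm, sperm], tolerance = 1e-12)
})

test_that("zero-variance stimuli are excluded with a warning", {
  set.seed(17)
  acts <- matrix(rnorm(5 * 8), 5, 8)
  acts[3, ] <- 2
  expect_warning(r <- compute_rdm(acts), "zero-variance")
  expect_identical(r$n_stimuli, 4L)
  expect_identical(r$excluded, 3L)
})

test_that("RDM correlation behaves at its fixed points and under the null", {
  set.seed(18)
  a <- compute_rdm(matrix(rnorm(10 * 6), 10, 6))
  expect_equal(rdm_correlation(a, a), 1)
  b <- a$values
  b[lower.tri(b) | upper.tri(b)] <- 1 - b[lower.tri(b) | upper.tri(b)]
  expect_equal(rdm_correlation(a, b), -1, tolerance = 1e-12)
  expect_error(rdm_correlation(a, compute_rdm(matrix(rnorm(4 * 6), 4, 6))),
               "different stimulus sets")

  # independently shuffled raw distances decorrelate
  set.seed(19)
  n <- 50
  raw <- as.matrix(dist(matrix(rnorm(n * 4), n, 4)))
  rs <- vapply(1:20, function(i) {
    shuf <- function() {
      v <- sample(raw[lower.tri(raw)])
      m <- matrix(0, n, n); m[lower.tri(m)] <- v
      m + t(m)
    }
    a <- shuf(); b <- shuf()
    cor(a[lower.tri(raw)], b[lower.tri(raw)])
  }, numeric(1))
  expect_true(all(abs(rs) < 0.1))
})

test_that("split-half reliability is high for duplicated filters, null for noise", {
  set.seed(20)
  base <- matrix(rnorm(12 * 6), 12, 6)    # 12 stimuli x 6 filters, signal
  dup <- cbind(base, base)                # each filter duplicated
  # forced split separating the copies: identical representations
  r1 <- compute_rdm(dup[, 1:6]); r2 <- compute_rdm(dup[, 7:12])
  expect_equal(rdm_correlation(r1, r2), 1)
  # random splits share duplicated information but mix copies: high, not 1
  expect_gt(as.numeric(split_half_reliability(dup, n_splits = 10, seed = 1)),
            0.4)
  # pure-noise activations per filter (many weak features): near zero
  noise <- matrix(rnorm(12 * 40), 12, 40)
  rel <- as.numeric(split_half_reliability(noise, n_splits = 10, seed = 2))
  expect_lt(abs(rel), 0.35)
  s1 <- split_half_reliability(dup, n_splits = 5, seed = 7)
  s2 <- split_half_reliability(dup, n_splits = 5, seed = 7)
  expect_identical(s1, s2)
  expect_error(split_half_reliability(matrix(rnorm(12), 4, 3)), "4 filters")
})

test_that("cross-layer table covers all pairs with split-half diagonals", {
  m <- tiny_trained()$model
  stim <- generate_rdm_stimulus_set(tiny_dataset(), 2, seed = 5)
  tab <- cross_layer_matrix(m, stim, n_splits = 3, seed = 1)
  expect_identical(nrow(tab), 10L)         # 4 combos -> 4*5/2 pairs
  expect_identical(sum(tab$type == "split_half"), 4L)
  expect_true(all(abs(tab$r) <= 1 + 1e-12))
  bsr <- between_stream_rdm(tab)
  expect_identical(bsr$layer, c("conv1", "conv2"))
})
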
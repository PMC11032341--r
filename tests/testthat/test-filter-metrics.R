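test_that("flatness screening separates structured from flat kernels", {
  expect_true(flatness_test(make_filter(filter_spec("flat"))))
  expect_false(flatness_test(make_filter(filter_spec("gabor", sf_cycles = 2))))
  # one flat channel does not make the whole kernel flat
  k <- make_filter(filter_spec("gabor", sf_cycles = 2, hue = c(1, 0, 1)))
  expect_false(flatness_test(k))
})

test_that("colour index follows the r_min formula and its special cases", {
  gray <- make_filter(filter_spec("gabor", orientation_deg = 60,
                                  sf_cycles = 2, hue = c(1, 1, 1)))
  ci <- color_index(gray)
  expect_equal(ci$r_min, 1)
  expect_equal(ci$color_index, 0)
  # flat G channel: correlation undefined, index pinned to 1
  flatg <- make_filter(filter_spec("gabor", sf_cycles = 2, hue = c(1, 0, 1)))
  expect_identical(color_index(flatg)$color_index, 1)
  expect_true(is.na(color_index(flatg)$r_min))
  # R = -G = B: perfect opponency
  opp <- make_filter(filter_spec("gabor", sf_cycles = 3, hue = c(1, -1, 1)))
  expect_equal(color_index(opp)$r_min, -1)
  expect_equal(color_index(opp)$color_index, 1)
  expect_error(color_index(make_filter(filter_spec("flat"))), "flat")
})

test_that("colour index is invariant under positive channel-wise affine maps", {
  k <- random_kernel(seed = 7)
  ci0 <- color_index(k)$color_index
  k2 <- k
  for (c in 1:3) k2$weights[, , c] <- 2.5 * k2$weights[, , c] + c * 0.3
  expect_equal(color_index(k2)$color_index, ci0, tolerance = 1e-12)
  expect_gte(ci0, 0); expect_lte(ci0, 1)
})

test_that("preferred channel picks the largest spectral amplitude with R>G>B ties", {
  r_dom <- make_filter(filter_spec("color_blob", hue = c(1, 0.2, 0.1)))
  expect_identical(preferred_channel(r_dom), "R")
  gray <- make_filter(filter_spec("gabor", sf_cycles = 2, hue = c(1, 1, 1)))
  expect_identical(preferred_channel(gray), "R")    # exact tie -> R
  g2 <- make_filter(filter_spec("gabor", sf_cycles = 2, hue = c(1, 2, 1)))
  expect_identical(preferred_channel(g2), "G")
})

test_that("orientation index recovers Gabor orientation and blob isotropy", {
  iso <- make_filter(filter_spec("color_blob", hue = c(1, -0.5, 0.3)))
  expect_lt(orientation_index(iso)$orientation_index, 0.05)
  vert <- make_filter(filter_spec("gabor", orientation_deg = 90,
                                  sf_cycles = 2))
  oi <- orientation_index(vert)
  expect_gt(oi$orientation_index, 0.9)
  expect_identical(oi$preferred_orientation_deg, 90)
  # orthogonal bin nearly empty
  expect_lt(oi$bin_amplitudes[1] / max(oi$bin_amplitudes), 0.05)
})

test_that("rotating a kernel by 90 degrees rotates its preferred orientation", {
  for (orient in c(0, 30, 60)) {
    k <- make_filter(filter_spec("gabor", orientation_deg = orient,
                                 sf_cycles = 3, hue = c(1, 0.5, 0.2)))
    rot <- k
    for (c in 1:3) rot$weights[, , c] <- t(k$weights[, , c])[11:1, ]
    a <- orientation_index(k); b <- orientation_index(rot)
    expect_equal(b$orientation_index, a$orientation_index, tolerance = 1e-9)
    expect_equal(b$preferred_orientation_deg,
                 (a$preferred_orientation_deg + 90) %% 180)
  }
})

test_that("preferred SF recovers pure radial frequencies and is sign-invariant", {
  k <- 11
  for (f in 1:5) {
    x <- matrix(rep(cos(2 * pi * f * (0:(k - 1)) / k), each = k), k, k,
                byrow = TRUE)
    kern <- filter_kernel(array(rep(x, 3), c(k, k, 3)))
    expect_identical(preferred_sf(kern)$preferred_sf, f)
    neg <- kern; neg$weights <- -neg$weights
    expect_equal(preferred_sf(neg)$sf_amplitudes,
                 preferred_sf(kern)$sf_amplitudes, tolerance = 1e-12)
  }
  blob <- make_filter(filter_spec("color_blob", hue = c(1, 0.1, 0.1)))
  expect_identical(preferred_sf(blob)$preferred_sf, 0L)
})

test_that("the Gabor bank's tuning is recovered wherever the DFT grid can express it", {
  bk <- gabor_bank(size = 11)
  tab <- analyze_filter_bank(bk$kernels)
  expect_false(any(tab$is_flat))
  # SF recovery is exact everywhere
  expect_identical(as.integer(tab$preferred_sf), as.integer(bk$truth$sf))
  # orientation recovery: exact for SF >= 2; at SF 1 only the cardinal
  # orientations are representable on an 11-point grid (an oblique
  # one-cycle carrier's spectral peak is equidistant from the lattice
  # points in the two neighbouring bins)
  representable <- bk$truth$sf >= 2 | bk$truth$orientation %in% c(0, 90)
  expect_true(all(tab$preferred_orientation_deg[representable] ==
                    bk$truth$orientation[representable]))
  expect_true(all(tab$orientation_index[bk$truth$sf >= 2] > 0.5))
})

test_that("bank analysis flags flat kernels and withholds their indices", {
  kernels <- c(gabor_bank(orientations = c(0, 60), sfs = 2:3)$kernels,
               list(make_filter(filter_spec("flat")),
                    make_filter(filter_spec("flat"))))
  tab <- analyze_filter_bank(kernels)
  expect_identical(nrow(tab), 6L)
  expect_identical(sum(tab$is_flat), 2L)
  expect_identical(sum(!is.na(tab$color_index)), 4L)
  expect_true(all(is.na(tab$color_index[tab$is_flat])))
})
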
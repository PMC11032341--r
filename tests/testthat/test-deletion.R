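test_that("per-category accuracy counts exactly and flags empty categories", {
  tr <- tiny_trained()
  ds <- tiny_dataset()
  tab <- per_category_accuracy(tr$model, ds$eval$x, ds$eval$y, ds$categories)
  # enumeration oracle: recount from the raw predictions
  pred <- predict_classes(tr$model, ds$eval$x)
  for (i in seq_len(nrow(tab))) {
    sel <- ds$eval$y == tab$category_id[i]
    expect_identical(tab$top1[i], mean(pred[sel] == tab$category_id[i]))
    expect_identical(tab$n_eval[i], sum(sel))
  }
  # a category with zero eval images is flagged and dropped
  cats2 <- rbind(ds$categories[, c("category_id", "super_category")],
                 data.frame(category_id = 99L, super_category = "B"))
  expect_warning(tab2 <- per_category_accuracy(tr$model, ds$eval$x, ds$eval$y,
                                               cats2), "zero eval")
  expect_false(99 %in% tab2$category_id)
})

test_that("a constant-output classifier scores 1 on its class and 0 elsewhere", {
  m <- build_model(tiny_arch(), seed = 30)
  ds <- tiny_dataset()
  m$classes <- sort(unique(ds$train$y))
  last <- length(m$fc)
  m$fc[[last]]$W[] <- 0
  m$fc[[last]]$b[] <- 0
  m$fc[[last]]$b[3] <- 10          # always predicts class 3
  tab <- per_category_accuracy(m, ds$eval$x, ds$eval$y, ds$categories)
  expect_identical(tab$top1, c(0, 0, 1, 0))
})

test_that("deleting a stream with all-zero weights changes nothing", {
  tr <- tiny_trained()
  ds <- tiny_dataset()
  m <- tr$model
  for (l in seq_along(m$streams[[2]])) {
    m$streams[[2]][[l]]$W[] <- 0
    m$streams[[2]][[l]]$b[] <- 0
  }
  intact <- per_category_accuracy(m, ds$eval$x, ds$eval$y, ds$categories)
  deleted <- per_category_accuracy(with_stream_deleted(m, 2, "zero"),
                                   ds$eval$x, ds$eval$y, ds$categories)
  expect_identical(intact, deleted)
  dt <- delta_accuracy(intact, deleted)
  expect_identical(dt$delta, rep(0, 4))
  expect_true(all(dt$delta >= -1 & dt$delta <= 1))
})

test_that("rank-walk AUC matches pair counting, with ties as diagonals", {
  # perfect separation
  r <- rank_walk_auc(c(5, 4, 3, 2, 1, 0), rep(c("A", "B"), each = 3))
  expect_identical(r$auc, 1)
  # interleaved, strictly decreasing, equal counts: the A-first interleave
  # gives (n+1)/(2n) by pair counting, the B-first one (n-1)/(2n); the two
  # interleavings average to the symmetric 0.5
  r2 <- rank_walk_auc(6:1, rep(c("A", "B"), 3))
  expect_identical(r2$auc, 2 / 3)
  r2b <- rank_walk_auc(6:1, rep(c("B", "A"), 3))
  expect_identical(r2b$auc, 1 / 3)
  expect_identical((r2$auc + r2b$auc) / 2, 0.5)
  # all deltas identical: fully diagonal walk
  r3 <- rank_walk_auc(rep(0.2, 8), rep(c("A", "B"), 4))
  expect_identical(r3$auc, 0.5)
  expect_identical(r3$walk$x, c(0, 4))
  expect_identical(r3$walk$y, c(0, 4))

  for (seed in 1:50) {
    tb <- random_delta_table(seed)
    auc <- rank_walk_auc(tb$delta, tb$super)$auc
    expect_equal(auc, oracle_pair_auc(tb$delta, tb$super == "A"),
                 tolerance = 1e-12)
    # label swap maps auc to 1 - auc
    expect_equal(rank_walk_auc(tb$delta, tb$super, super_a = "B")$auc,
                 1 - auc, tolerance = 1e-12)
    # internal midrank formulation agrees with the walk
    expect_equal(parastream:::.auc_midrank(tb$delta, tb$super == "A"), auc,
                 tolerance = 1e-12)
  }
  expect_error(rank_walk_auc(1:3, rep("A", 3)), "at least one category")
})

test_that("permutation test calibrates against its exchangeable null", {
  # perfect separation, n_A = n_B = 10: add-one two-tailed bound
  delta <- c(seq(1, 0.1, length.out = 10), seq(-0.1, -1, length.out = 10))
  super <- rep(c("A", "B"), each = 10)
  pt <- permutation_test(delta, super, n_permutations = 1000, seed = 2)
  expect_identical(pt$auc, 1)
  expect_lte(pt$p_value, 0.002)
  expect_lt(abs(mean(pt$null) - 0.5), 0.02)
  # an observed AUC at the null median is non-significant
  tb <- random_delta_table(7)
  set.seed(41)
  pt2 <- permutation_test(sample(tb$delta), tb$super,
                          n_permutations = 500, seed = 3)
  expect_gt(pt2$p_value, 0.05)
  expect_warning(permutation_test(delta, super, n_permutations = 50,
                                  seed = 1), "100 permutations")
  # determinism
  pa <- permutation_test(delta, super, n_permutations = 200, seed = 9)
  pb <- permutation_test(delta, super, n_permutations = 200, seed = 9)
  expect_identical(pa$null, pb$null)
})

test_that("deletion-mode comparison reports AUC per stream and mode", {
  tr <- tiny_trained()
  ds <- tiny_dataset()
  res <- compare_deletion_modes(tr$model, ds$eval$x, ds$eval$y,
                                ds$categories, n_permutations = 200, seed = 4)
  expect_identical(nrow(res$auc_table), 4L)
  expect_true(all(res$auc_table$auc >= 0 & res$auc_table$auc <= 1))
  # 2 streams -> 2 mode pairs: rank correlation degenerate, flagged NA
  expect_true(is.na(res$mode_rank_correlation))

  # a stream with no information: both modes give delta 0, auc exactly 0.5
  m <- tr$model
  for (l in seq_along(m$streams[[1]])) {
    m$streams[[1]][[l]]$W[] <- 0
    m$streams[[1]][[l]]$b[] <- 0
  }
  res0 <- compare_deletion_modes(m, ds$eval$x, ds$eval$y, ds$categories,
                                 streams = 1, n_permutations = 100, seed = 1)
  expect_true(all(vapply(res0$delta_tables, function(t) all(t$delta == 0),
                         logical(1))))
  expect_true(all(res0$auc_table$auc == 0.5))
})
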
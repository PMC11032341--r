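# Stream-deletion experiment: per-category top-1 accuracy for intact vs
# stream-deleted models, the drop in accuracy per category, and a rank-walk
# AUC over the two super-categories with a label-permutation test. The AUC
# is the area under the cumulative super-category step plot of categories
# sorted by accuracy drop, normalized by the product of the super-category
# sizes; with midrank tie handling it equals the Mann-Whitney U statistic
# divided by n_A * n_B.

#' Per-category top-1 accuracy
#'
#' @param net a `stream_net` or deletion view from [with_stream_deleted()].
#' @param x (H, W, 3, N) eval images.
#' @param y category labels.
#' @param categories optional category table with `category_id` and
#'   `super_category` (e.g. `dataset$categories`); categories with zero eval
#'   images are flagged and excluded.
#' @param batch_size forward batch size.
#' @return data.frame with `category_id`, `super_category` (if supplied),
#'   `n_eval`, `top1`.
#' @export
per_category_accuracy <- function(net, x, y, categories = NULL,
                                  batch_size = 128) {
  pred <- predict_classes(net, x, batch_size = batch_size)
  ids <- if (!is.null(categories)) categories$category_id else sort(unique(y))
  rows <- lapply(ids, function(id) {
    sel <- y == id
    data.frame(category_id = id,
               n_eval = sum(sel),
               top1 = if (sum(sel) > 0) mean(pred[sel] == id) else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (!is.null(categories)) {
    out$super_category <- categories$super_category[match(out$category_id,
                                                          categories$category_id)]
    out <- out[, c("category_id", "super_category", "n_eval", "top1")]
  }
  dropped <- out$n_eval == 0
  if (any(dropped)) {
    warning(sprintf("%d categories with zero eval images excluded",
                    sum(dropped)))
    out <- out[!dropped, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Accuracy drop per category under stream deletion
#'
#' @param intact,deleted per-category accuracy tables from
#'   [per_category_accuracy()] for the intact and stream-deleted model.
#' @return the intact table plus `top1_deleted` and
#'   `delta = top1 - top1_deleted`.
#' @export
delta_accuracy <- function(intact, deleted) {
  .assert(identical(intact$category_id, deleted$category_id),
          "tables cover different categories")
  out <- intact
  names(out)[names(out) == "top1"] <- "top1_intact"
  out$top1_deleted <- deleted$top1
  out$delta <- out$top1_intact - out$top1_deleted
  out
}

# Midrank formulation of the normalized AUC (used for fast permutations;
# provably equal to the rank-walk construction, which the tests assert).
.auc_midrank <- function(delta, is_a) {
  n_a <- sum(is_a); n_b <- sum(!is_a)
  r <- rank(delta, ties.method = "average")
  (sum(r[is_a]) - n_a * (n_a + 1) / 2) / (n_a * n_b)
}

#' Rank-walk AUC over super-categories
#'
#' Categories are sorted by `delta` (accuracy drop) in descending order and
#' replotted as a walk in the x-y plane: each super-A category is a unit
#' vertical step, each super-B category a unit horizontal step; a group of
#' tied deltas is traversed as a single diagonal segment (equivalently,
#' midranks), making the result independent of tie order. The area under
#' the walk divided by `n_A * n_B` is the AUC: 1 when every A-category
#' outranks every B-category, 0.5 for no super-category bias (all deltas
#' equal gives exactly 0.5), and it equals the probability that a random
#' A-category outranks a random B-category with ties counted 1/2.
#'
#' @param delta numeric vector of per-category accuracy drops (or any score).
#' @param super super-category labels, two levels.
#' @param super_a which level plays the vertical ("A") role (default
#'   `"A"`).
#' @return object of class `auc_result`: `auc`, `n_super_a`, `n_super_b`,
#'   `walk` (data.frame of x-y vertices).
#' @export
rank_walk_auc <- function(delta, super, super_a = "A") {
  .assert(length(delta) == length(super), "delta and super differ in length")
  is_a <- super == super_a
  n_a <- sum(is_a); n_b <- sum(!is_a)
  .assert(n_a >= 1 && n_b >= 1, "need at least one category per super-category")
  ord <- order(delta, decreasing = TRUE)
  d_sorted <- delta[ord]
  a_sorted <- is_a[ord]
  x <- 0; y <- 0; area <- 0
  xs <- 0; ys <- 0
  i <- 1
  while (i <= length(d_sorted)) {
    j <- i
    while (j < length(d_sorted) && d_sorted[j + 1] == d_sorted[i]) j <- j + 1
    a <- sum(a_sorted[i:j])        # vertical steps in this tie group
    b <- (j - i + 1) - a           # horizontal steps
    area <- area + b * y + a * b / 2   # diagonal segment across the group
    x <- x + b; y <- y + a
    xs <- c(xs, x); ys <- c(ys, y)
    i <- j + 1
  }
  structure(list(auc = area / (n_a * n_b), n_super_a = n_a, n_super_b = n_b,
                 walk = data.frame(x = xs, y = ys)),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result auc = %.4f (n_A = %d, n_B = %d)%s>\n", x$auc,
              x$n_super_a, x$n_super_b,
              if (!is.null(x$p_value)) sprintf(", p = %.4g", x$p_value) else ""))
  invisible(x)
}

#' Permutation test for a rank-walk AUC
#'
#' Null AUCs are generated by permuting the super-category labels while
#' holding the deltas fixed. The p-value is two-tailed with the add-one
#' correction: `p = min(1, 2 * min(p_hi, p_lo))` where
#' `p_hi = (1 + #\{null >= observed\}) / (n_permutations + 1)` and `p_lo`
#' symmetric.
#'
#' @inheritParams rank_walk_auc
#' @param n_permutations number of label randomizations (default 1000; a
#'   warning is logged below 100).
#' @param seed integer seed.
#' @return `auc_result` with `p_value`, `null` (the null sample),
#'   `n_permutations`, `seed` added.
#' @export
permutation_test <- function(delta, super, super_a = "A",
                             n_permutations = 1000, seed = 1) {
  if (n_permutations < 100) {
    warning("fewer than 100 permutations gives a coarse p-value")
  }
  res <- rank_walk_auc(delta, super, super_a = super_a)
  is_a <- super == super_a
  null <- .with_seed(seed, vapply(seq_len(n_permutations), function(i) {
    .auc_midrank(delta, sample(is_a))
  }, numeric(1)))
  p_hi <- (1 + sum(null >= res$auc)) / (n_permutations + 1)
  p_lo <- (1 + sum(null <= res$auc)) / (n_permutations + 1)
  res$p_value <- min(1, 2 * min(p_hi, p_lo))
  res$null <- null
  res$n_permutations <- as.integer(n_permutations)
  res$seed <- as.integer(seed)
  res
}

#' Stream-deletion experiment across streams and deletion modes
#'
#' Evaluates the intact model once, then every (stream, mode) deletion,
#' computing the per-category accuracy drop, AUC, and permutation p-value.
#' Also reports the rank correlation between the zero-mode and mean-mode
#' AUC vectors (undefined with fewer than 3 pairs).
#'
#' @param model a trained `stream_net`.
#' @param x,y eval images and labels.
#' @param categories category table with `category_id` and `super_category`.
#' @param streams streams to delete (default all).
#' @param modes deletion modes (default both `"zero"` and `"mean"`).
#' @param super_a super-category playing the vertical role in the AUC.
#' @param n_permutations,seed permutation test parameters.
#' @param batch_size forward batch size.
#' @return list with `auc_table` (one row per stream x mode: auc, p_value),
#'   `mode_rank_correlation` (Spearman, or NA if < 3 pairs), `delta_tables`
#'   (named list of per-category tables), `intact` (intact accuracy table).
#' @export
compare_deletion_modes <- function(model, x, y, categories,
                                   streams = NULL, modes = c("zero", "mean"),
                                   super_a = "A", n_permutations = 1000,
                                   seed = 1, batch_size = 128) {
  net <- .resolve_net(model)
  if (is.null(streams)) streams <- seq_len(net$model$arch$n_streams)
  intact <- per_category_accuracy(net$model, x, y, categories,
                                  batch_size = batch_size)
  rows <- list(); deltas <- list()
  for (s in streams) {
    for (m in modes) {
      view <- with_stream_deleted(net$model, s, m)
      tab <- per_category_accuracy(view, x, y, categories,
                                   batch_size = batch_size)
      dt <- delta_accuracy(intact, tab)
      pt <- permutation_test(dt$delta, dt$super_category, super_a = super_a,
                             n_permutations = n_permutations, seed = seed)
      rows[[length(rows) + 1L]] <-
        data.frame(stream = s, mode = m, auc = pt$auc, p_value = pt$p_value,
                   n_super_a = pt$n_super_a, n_super_b = pt$n_super_b,
                   stringsAsFactors = FALSE)
      deltas[[paste0("stream", s, "_", m)]] <- dt
    }
  }
  auc_table <- do.call(rbind, rows)
  mode_cor <- NA_real_
  if (all(c("zero", "mean") %in% modes)) {
    za <- auc_table$auc[auc_table$mode == "zero"]
    ma <- auc_table$auc[auc_table$mode == "mean"]
    if (length(za) >= 3) {
      mode_cor <- stats::cor(za, ma, method = "spearman")
    }
  }
  list(auc_table = auc_table, mode_rank_correlation = mode_cor,
       delta_tables = deltas, intact = intact)
}
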
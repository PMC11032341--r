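# Instance-level orchestration and the statistical battery: between-stream
# comparisons of tuning indices (Mann-Whitney / Kruskal-Wallis), rank
# correlations among metrics, inheritance of between-stream differences
# into deeper layers, AUC-vs-selectivity relationships, and the layerwise
# RDM trend (Friedman). Population summaries use the median, except the
# first layer's preferred SF, which is summarized by the mean (its
# distribution is too discrete for medians to separate groups).

.metric_summary_fun <- function(metric) {
  if (metric == "preferred_sf") {
    function(v) mean(v, na.rm = TRUE)
  } else {
    function(v) stats::median(v, na.rm = TRUE)
  }
}

#' Between-stream comparison of a tuning metric
#'
#' Two streams are compared with the two-tailed Mann-Whitney U test
#' (`wilcox.test`); three or more with the Kruskal-Wallis H test. Flat
#' filters are excluded. Streams are summarized by the median (mean for
#' `preferred_sf`).
#'
#' @param records filter-bank table from [analyze_filter_bank()] (rows from
#'   several streams, `stream` column set).
#' @param metric column to compare: `"color_index"`, `"orientation_index"`
#'   or `"preferred_sf"`.
#' @param alpha significance threshold (default 0.01).
#' @return list with `test`, `statistic`, `p_value`, `significant`,
#'   `summaries` (named per-stream values), `n` (per-stream counts). When a
#'   stream has fewer than 2 usable filters the test is undefined-flagged
#'   (`p_value = NA`).
#' @export
compare_streams <- function(records, metric = "color_index", alpha = 0.01) {
  .assert(metric %in% names(records), sprintf("no column '%s'", metric))
  use <- records[!records$is_flat & !is.na(records[[metric]]), , drop = FALSE]
  streams <- sort(unique(records$stream))
  vals <- lapply(streams, function(s) use[[metric]][use$stream == s])
  names(vals) <- paste0("stream", streams)
  sfun <- .metric_summary_fun(metric)
  summaries <- vapply(vals, sfun, numeric(1))
  ns <- vapply(vals, length, integer(1))
  if (any(ns < 2)) {
    return(list(test = NA_character_, statistic = NA_real_,
                p_value = NA_real_, significant = NA,
                summaries = summaries, n = ns,
                note = "a stream has fewer than 2 non-flat filters"))
  }
  if (length(streams) == 2) {
    ht <- suppressWarnings(stats::wilcox.test(vals[[1]], vals[[2]],
                                              alternative = "two.sided"))
    test <- "Mann-Whitney U (two-tailed)"
  } else {
    ht <- stats::kruskal.test(vals)
    test <- "Kruskal-Wallis H"
  }
  list(test = test, statistic = unname(ht$statistic), p_value = ht$p.value,
       significant = ht$p.value < alpha, summaries = summaries, n = ns)
}

#' Rank correlations among the tuning metrics
#'
#' Spearman correlations between each pair of `color_index`,
#' `orientation_index` and `preferred_sf` across the non-flat filters of a
#' bank.
#'
#' @param records table from [analyze_filter_bank()].
#' @param alpha significance threshold.
#' @return data.frame with `metric_a`, `metric_b`, `rho`, `p_value`, `n`,
#'   `significant` (NA rho when a metric is degenerate/constant).
#' @export
metric_correlations <- function(records, alpha = 0.01) {
  use <- records[!records$is_flat, , drop = FALSE]
  metrics <- c("color_index", "orientation_index", "preferred_sf")
  pairs <- utils::combn(metrics, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- use[[pairs[1, i]]]; b <- use[[pairs[2, i]]]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(data.frame(metric_a = pairs[1, i], metric_b = pairs[2, i],
                        rho = NA_real_, p_value = NA_real_, n = length(a),
                        significant = NA))
    }
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
    data.frame(metric_a = pairs[1, i], metric_b = pairs[2, i],
               rho = unname(ct$estimate), p_value = ct$p.value, n = length(a),
               significant = ct$p.value < alpha)
  })
  do.call(rbind, rows)
}

#' Inheritance of between-stream differences into deeper layers
#'
#' Across model instances, correlates the absolute between-stream difference
#' of the conv1 colour index with that of each deeper layer's MES colour
#' index: a positive correlation means first-layer segregation is inherited
#' up the hierarchy.
#'
#' @param instances data.frame with columns `instance`, `layer`,
#'   `conv1_abs_diff`, `deep_abs_diff` (one row per instance x deeper layer).
#' @param alpha significance threshold.
#' @return data.frame per layer: `rho`, `p_value`, `n`, `significant`;
#'   undefined-flagged with fewer than 3 instances.
#' @export
inheritance_analysis <- function(instances, alpha = 0.01) {
  layers <- unique(instances$layer)
  rows <- lapply(layers, function(l) {
    d <- instances[instances$layer == l, , drop = FALSE]
    if (nrow(d) < 3 || stats::sd(d$conv1_abs_diff) == 0 ||
        stats::sd(d$deep_abs_diff) == 0) {
      return(data.frame(layer = l, rho = NA_real_, p_value = NA_real_,
                        n = nrow(d), significant = NA))
    }
    ct <- suppressWarnings(stats::cor.test(d$conv1_abs_diff, d$deep_abs_diff,
                                           method = "spearman"))
    data.frame(layer = l, rho = unname(ct$estimate), p_value = ct$p.value,
               n = nrow(d), significant = ct$p.value < alpha)
  })
  do.call(rbind, rows)
}

#' AUC versus first-layer selectivity
#'
#' Pools per-stream rows across instances and rank-correlates each stream's
#' deletion AUC with its first-layer tuning summaries.
#'
#' @param stream_table data.frame with one row per (instance, stream):
#'   `auc`, `median_color_index`, `median_orientation_index`,
#'   `mean_preferred_sf`.
#' @param alpha significance threshold.
#' @return data.frame per selectivity summary: `rho`, `p_value`, `n`,
#'   `significant` (NA when the AUC or the summary is constant).
#' @export
auc_vs_selectivity <- function(stream_table, alpha = 0.01) {
  metrics <- intersect(c("median_color_index", "median_orientation_index",
                         "mean_preferred_sf"), names(stream_table))
  rows <- lapply(metrics, function(m) {
    a <- stream_table$auc; b <- stream_table[[m]]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(data.frame(metric = m, rho = NA_real_, p_value = NA_real_,
                        n = length(a), significant = NA))
    }
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
    data.frame(metric = m, rho = unname(ct$estimate), p_value = ct$p.value,
               n = length(a), significant = ct$p.value < alpha)
  })
  do.call(rbind, rows)
}

#' Layerwise trend of between-stream RDM correlation
#'
#' Tests whether the between-stream RDM correlation differs across layers
#' with instances as repeated samples: Friedman test for 3+ layers, paired
#' Wilcoxon for exactly 2; with fewer than 3 instances the trend is
#' reported without a test.
#'
#' @param profiles numeric matrix, instances x layers (between-stream RDM
#'   correlation per layer); column names are layer names.
#' @param alpha significance threshold.
#' @return list with `medians` (per layer), `test`, `statistic`, `p_value`,
#'   `significant`.
#' @export
layerwise_rdm_trend <- function(profiles, alpha = 0.01) {
  profiles <- as.matrix(profiles)
  medians <- apply(profiles, 2, stats::median)
  if (nrow(profiles) < 3) {
    return(list(medians = medians, test = NA_character_,
                statistic = NA_real_, p_value = NA_real_, significant = NA,
                note = "fewer than 3 instances: trend reported without a test"))
  }
  if (ncol(profiles) >= 3) {
    ht <- stats::friedman.test(profiles)
    test <- "Friedman (repeated samples)"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(profiles[, 1], profiles[, 2],
                                              paired = TRUE))
    test <- "Wilcoxon signed-rank (paired)"
  }
  list(medians = medians, test = test, statistic = unname(ht$statistic),
       p_value = ht$p.value, significant = ht$p.value < alpha)
}
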
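# Fixture banks with planted segregation: one stream of colour-opponent
# blobs, one of achromatic Gabors.
planted_records <- function(n_per_stream = 12) {
  blobs <- lapply(seq_len(n_per_stream), function(i) {
    hue <- list(c(1, -0.8, 0.1), c(-0.5, 1, -0.4), c(0.2, -0.6, 1))[[i %% 3 + 1]]
    k <- make_filter(filter_spec("color_blob", hue = hue * (0.8 + 0.02 * i)))
    k$stream <- 1L; k$index <- i
    k
  })
  gabors <- lapply(seq_len(n_per_stream), function(i) {
    k <- make_filter(filter_spec("gabor",
                                 orientation_deg = (i * 30) %% 180,
                                 sf_cycles = 2 + i %% 3, hue = c(1, 1, 1)))
    k$stream <- 2L; k$index <- i
    k
  })
  analyze_filter_bank(c(blobs, gabors))
}

test_that("between-stream comparison detects planted segregation", {
  rec <- planted_records()
  cmp <- compare_streams(rec, "color_index", alpha = 0.01)
  expect_identical(cmp$test, "Mann-Whitney U (two-tailed)")
  expect_true(cmp$significant)
  expect_gt(cmp$summaries[["stream1"]], cmp$summaries[["stream2"]])
  # orientation separates the other way
  cmp_o <- compare_streams(rec, "orientation_index", alpha = 0.01)
  expect_true(cmp_o$significant)
  expect_lt(cmp_o$summaries[["stream1"]], cmp_o$summaries[["stream2"]])
  # preferred SF is summarized by the mean
  cmp_sf <- compare_streams(rec, "preferred_sf")
  expect_identical(cmp_sf$summaries[["stream1"]],
                   mean(rec$preferred_sf[rec$stream == 1]))
})

test_that("identical streams are not flagged and edge cases are NA-flagged", {
  # a genuinely identical pair with varied values: duplicate a random bank
  rks <- lapply(1:10, function(i) {
    k <- random_kernel(size = 7, seed = i); k$stream <- 1L; k$index <- i; k
  })
  s1 <- analyze_filter_bank(rks)
  s2 <- s1; s2$stream <- 2L
  cmp <- compare_streams(rbind(s1, s2), "color_index")
  expect_false(cmp$significant)
  expect_identical(cmp$summaries[["stream1"]], cmp$summaries[["stream2"]])

  # all-flat stream
  flats <- analyze_filter_bank(c(
    lapply(1:3, function(i) {
      k <- make_filter(filter_spec("flat")); k$stream <- 1L; k
    }),
    lapply(1:3, function(i) {
      k <- make_filter(filter_spec("gabor", sf_cycles = 2)); k$stream <- 2L; k
    })
  ))
  cmp2 <- compare_streams(flats, "color_index")
  expect_true(is.na(cmp2$p_value))
})

test_that("three streams route to the Kruskal-Wallis branch", {
  rec <- planted_records()
  rec3 <- rec
  rec3$stream <- rep(1:3, length.out = nrow(rec3))
  cmp <- compare_streams(rec3, "color_index")
  expect_identical(cmp$test, "Kruskal-Wallis H")
  expect_length(cmp$summaries, 3L)
})

test_that("metric correlations recover planted orderings", {
  rec <- planted_records()
  mc <- metric_correlations(rec)
  # colour blobs are low-SF, Gabors high-SF: colour vs SF negative
  row <- mc[mc$metric_a == "color_index" & mc$metric_b == "preferred_sf", ]
  expect_lt(row$rho, -0.5)
  # colour and orientation indices anti-ordered in this fixture
  row2 <- mc[mc$metric_a == "color_index" &
               mc$metric_b == "orientation_index", ]
  expect_lt(row2$rho, -0.5)

  # independent random metrics: weak, non-significant correlation
  set.seed(77)
  fake <- data.frame(is_flat = FALSE, color_index = runif(100),
                     orientation_index = runif(100),
                     preferred_sf = sample(0:5, 100, TRUE))
  mcf <- metric_correlations(fake)
  expect_true(all(abs(mcf$rho) < 0.3))
  expect_false(any(mcf$significant))
})

test_that("inheritance analysis tracks planted and shuffled pairings", {
  set.seed(55)
  d1 <- runif(10)
  planted <- data.frame(instance = 1:10, layer = "conv2",
                        conv1_abs_diff = d1, deep_abs_diff = d1 * 0.7 + 0.1)
  ia <- inheritance_analysis(planted)
  expect_equal(ia$rho, 1)
  shuffled <- planted
  shuffled$deep_abs_diff <- sample(planted$deep_abs_diff)
  expect_lt(abs(inheritance_analysis(shuffled)$rho), 0.7)
  one <- inheritance_analysis(planted[1, ])
  expect_true(is.na(one$rho))
})

test_that("AUC-selectivity correlations respond to sign and degeneracy", {
  st <- data.frame(auc = c(0.5, 0.6, 0.7, 0.8),
                   median_color_index = c(0.1, 0.3, 0.5, 0.9),
                   median_orientation_index = c(0.9, 0.5, 0.3, 0.1),
                   mean_preferred_sf = c(2, 2, 2, 2))
  av <- auc_vs_selectivity(st)
  expect_equal(av$rho[av$metric == "median_color_index"], 1)
  expect_equal(av$rho[av$metric == "median_orientation_index"], -1)
  expect_true(is.na(av$rho[av$metric == "mean_preferred_sf"]))
  st2 <- st; st2$auc <- 0.6
  expect_true(all(is.na(auc_vs_selectivity(st2)$rho)))
})

test_that("layerwise RDM trend detects consistent decreases", {
  profiles <- matrix(rep(c(0.8, 0.5, 0.3), each = 6), 6, 3,
                     dimnames = list(NULL, c("conv1", "conv2", "conv3")))
  tr <- layerwise_rdm_trend(profiles)
  expect_identical(tr$test, "Friedman (repeated samples)")
  expect_lt(tr$p_value, 0.01)
  expect_identical(unname(tr$medians), c(0.8, 0.5, 0.3))

  set.seed(66)
  flat <- matrix(0.5 + rnorm(18, sd = 0.01), 6, 3)
  expect_gt(layerwise_rdm_trend(flat)$p_value, 0.01)

  two <- layerwise_rdm_trend(profiles[, 1:2])
  expect_identical(two$test, "Wilcoxon signed-rank (paired)")
  expect_true(is.na(layerwise_rdm_trend(profiles[1:2, ])$p_value))
})

test_that("the pipeline writes artifacts, resumes idempotently, and guards config", {
  out <- tempfile("pipe_")
  config <- list(
    dataset_spec = dataset_spec(n_categories = 4, n_train_per_category = 16,
                                n_eval_per_category = 4, image_size = 32,
                                seed = 2),
    arch = tiny_arch(),
    train = train_spec(epochs = 2, batch_size = 16, seed = 1),
    seeds = c(1, 2), out_dir = out, n_permutations = 100, rdm_splits = 3
  )
  s1 <- run_pipeline(config, verbose = FALSE)
  expect_identical(nrow(s1), 2L)
  expect_true(file.exists(file.path(out, "summary.csv")))
  expect_true(file.exists(file.path(out, "ckpt_seed1.rds")))
  expect_true(file.exists(file.path(out, "dataset", "categories.csv")))

  # rerun: cached stages, identical summaries
  s2 <- run_pipeline(config, verbose = FALSE)
  expect_equal(as.data.frame(lapply(s2, as.numeric)),
               as.data.frame(lapply(s1, as.numeric)), tolerance = 1e-12)

  # mismatched config refuses to mix
  config2 <- config
  config2$train <- train_spec(epochs = 3, batch_size = 16, seed = 1)
  expect_error(run_pipeline(config2, verbose = FALSE), "refusing to mix")
})
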
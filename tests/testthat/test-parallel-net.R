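test_that("model construction validates the plan and counts parameters analytically", {
  arch <- paper_arch()
  m <- build_model(arch, seed = 1)
  # analytic parameter count over the layer plan
  conv_per_stream <- function() {
    chans <- c(3, 48, 128, 192, 192)
    filt <- c(48, 128, 192, 192, 128)
    ks <- c(11, 5, 3, 3, 3)
    sum(ks^2 * chans * filt + filt)
  }
  fc_in <- 2 * arch$stream_units
  fc_params <- fc_in * 4096 + 4096 + 4096 * 4096 + 4096 +
    4096 * 1000 + 1000
  expect_identical(count_params(m), 2 * conv_per_stream() + fc_params)

  expect_error(stream_arch(1, list(conv_layer(4, 3)), 16, 4), "n_streams")
  expect_error(stream_arch(2, list(conv_layer(4, 9), conv_layer(4, 9)),
                           10, 4), "conv2")

  m2 <- build_model(arch, seed = 1)
  expect_identical(m$streams, m2$streams)
  m3 <- build_model(arch, seed = 2)
  expect_false(identical(m$streams[[1]][[1]]$W, m3$streams[[1]][[1]]$W))
})

test_that("kernel extraction is ordered, shaped, and checkpoint-stable", {
  m <- build_model(paper_arch(), seed = 3)
  ks <- get_kernels(m, "conv1", 1)
  expect_length(ks, 48)
  expect_identical(dim(ks[[1]]$weights), c(11L, 11L, 3L))
  expect_identical(ks[[7]]$index, 7L)
  expect_identical(ks[[7]]$weights, m$streams[[1]][[1]]$W[, , , 7])

  p <- tempfile(fileext = ".rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  expect_identical(m$streams, m2$streams)
  expect_error(get_kernels(m, "conv1", 5), "stream")
  expect_error(get_kernels(m, "conv9", 1), "conv9")
})

test_that("layer activations obey conv arithmetic, ReLU, and linearity", {
  m <- build_model(tiny_arch(), seed = 2)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  a1 <- layer_activations(m, x, "conv1", 1)
  # closed-form output size: (32 - 5)/2 + 1 = 14
  expect_identical(dim(a1), c(2L, 6L, 14L, 14L))
  expect_true(all(a1 >= 0))

  # zero input through a bias-free conv1 gives all-zero activations
  m0 <- m
  m0$streams[[1]][[1]]$b[] <- 0
  z <- layer_activations(m0, array(0, c(32, 32, 3, 1)), "conv1", 1)
  expect_identical(max(abs(z)), 0)

  # doubling contrast doubles the pre-ReLU response (bias-free)
  p1 <- layer_activations(m0, x, "conv1", 1, pre_activation = TRUE)
  p2 <- layer_activations(m0, 2 * x, "conv1", 1, pre_activation = TRUE)
  expect_equal(p2, 2 * p1, tolerance = 1e-12)

  expect_error(layer_activations(m, array(0, c(16, 16, 3, 1)), "conv1", 1),
               "32 x 32")
})

test_that("the learning-rate schedule applies step decays at the stated interval", {
  ds <- tiny_dataset()
  m <- build_model(tiny_arch(), seed = 4)
  tr <- train(m, ds, train_spec(epochs = 9, batch_size = 48,
                                lr_initial = 0.01, lr_decay_factor = 0.1,
                                lr_decay_every = 3, momentum = 0, seed = 1))
  expect_equal(unique(tr$log$lr), c(0.01, 0.001, 1e-4))
  expect_identical(nrow(tr$log), 9L)
  # 90 epochs decaying every 30 would apply exactly two decays
  lrs <- 0.01 * 0.1^((seq_len(90) - 1) %/% 30)
  expect_identical(length(unique(lrs)), 3L)

  # zero learning rate and momentum leave weights untouched
  tr0 <- train(m, ds, train_spec(epochs = 1, batch_size = 48,
                                 lr_initial = 0, momentum = 0, seed = 1))
  expect_identical(tr0$model$streams, m$streams)
  expect_identical(tr0$model$fc, m$fc)

  # reproducibility: same seeds and spec give identical loss curves
  tr2 <- train(m, ds, train_spec(epochs = 2, batch_size = 48, seed = 9))
  tr3 <- train(m, ds, train_spec(epochs = 2, batch_size = 48, seed = 9))
  expect_identical(tr2$log$train_loss, tr3$log$train_loss)
  expect_identical(tr2$model$streams, tr3$model$streams)
})

test_that("a trained tiny model beats chance comfortably", {
  tr <- tiny_trained()
  top1 <- tr$log$eval_top1[nrow(tr$log)]
  expect_gt(top1, 2 * 1 / 4)
})

test_that("stream deletion replaces exactly the targeted half of the code", {
  m <- tiny_trained()$model
  ds <- tiny_dataset()
  x <- ds$eval$x[, , , 1:8]
  units <- m$arch$stream_units

  intact <- parastream:::.net_forward(list(model = m, deleted = list()), x)
  v0 <- parastream:::.net_forward(
    parastream:::.resolve_net(with_stream_deleted(m, 1, "zero")), x)
  expect_identical(v0$flats[[1]], matrix(0, units, 8))
  expect_identical(v0$flats[[2]], intact$flats[[2]])   # survivor untouched

  vm <- parastream:::.net_forward(
    parastream:::.resolve_net(with_stream_deleted(m, 2, "mean")), x)
  expect_equal(unique(as.numeric(vm$flats[[2]])),
               mean(intact$flats[[2]]), tolerance = 1e-12)
  expect_identical(vm$flats[[1]], intact$flats[[1]])

  expect_error(with_stream_deleted(m, 1, "typo"))
  expect_error(with_stream_deleted(m, 7, "zero"), "stream")

  # deleting every stream leaves only FC biases: predictions constant
  both <- with_stream_deleted(with_stream_deleted(m, 1, "zero"), 2, "zero")
  pred <- predict_classes(both, x)
  expect_identical(length(unique(pred)), 1L)
})

test_that("permuting streams and concatenation slots preserves the classifier", {
  m <- tiny_trained()$model
  x <- tiny_dataset()$eval$x[, , , 1:6]
  units <- m$arch$stream_units
  m2 <- m
  m2$streams <- m$streams[c(2, 1)]
  perm <- c((units + 1):(2 * units), 1:units)
  m2$fc[[1]]$W <- m$fc[[1]]$W[, perm]
  expect_equal(predict_logits(m2, x), predict_logits(m, x), tolerance = 1e-10)
})
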
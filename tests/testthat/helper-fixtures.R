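# Shared fixtures built in code. The tiny dataset/model pair is cached per
# test session: several files exercise the same trained instance.

tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(dataset_spec(
        n_categories = 4, n_train_per_category = 24, n_eval_per_category = 6,
        image_size = 32, seed = 404
      ))
    }
    cache
  }
})

tiny_arch <- function(n_classes = 4, input_size = 32, n_streams = 2) {
  stream_arch(n_streams = n_streams,
              conv_layers = list(conv_layer(6, 5, stride = 2),
                                 conv_layer(8, 3)),
              input_size = input_size, n_classes = n_classes, fc_widths = 32)
}

tiny_trained <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- build_model(tiny_arch(), seed = 5)
      cache <<- train(m, tiny_dataset(),
                      train_spec(epochs = 20, batch_size = 8,
                                 lr_initial = 0.02, lr_decay_every = 8,
                                 momentum = 0.9, seed = 5))
    }
    cache
  }
})

random_kernel <- function(size = 11, seed = 1) {
  set.seed(seed)
  filter_kernel(array(rnorm(size * size * 3), c(size, size, 3)))
}

# Random per-category delta table with ties (deltas rounded to a coarse grid).
random_delta_table <- function(seed) {
  set.seed(seed)
  n_a <- sample(3:15, 1)
  n_b <- sample(3:15, 1)
  delta <- round(c(rnorm(n_a, 0.1), rnorm(n_b)), sample(1:2, 1))
  list(delta = delta, super = rep(c("A", "B"), c(n_a, n_b)))
}
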
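# Small fixtures built in code, shared across test files.

rand_image <- function(h, w, seed = 1, lo = 0, hi = 1) {
  set.seed(seed)
  matrix(stats::runif(h * w, lo, hi), h, w)
}

zero_mean_image <- function(h, w, seed = 1) {
  x <- rand_image(h, w, seed)
  x - mean(x)
}

# the shared-band, amplitude-decaying dataset used in the model experiments
experiment_spec <- function(images_per_class = 150L, seed = 21L) {
  band_dataset_spec(
    n_classes = 4L, images_per_class = images_per_class, size = c(32L, 32L),
    class_bands = matrix(rep(c(0.08, 1.0), each = 4), ncol = 2),
    template_components = 12L, amplitude_decay = 0.5, noise_std = 0.04,
    seed = seed)
}

split_dataset <- function(ds, test_every = 4L) {
  n <- length(ds$images)
  is_test <- (seq_len(n) %% test_every) == 0
  list(train = list(images = ds$images[!is_test], labels = ds$labels[!is_test]),
       test = list(images = ds$images[is_test], labels = ds$labels[is_test]))
}

# constant-prediction model for probe contracts
constant_model <- function(k, n_classes, input_shape) {
  classifier_handle(
    n_classes = n_classes, input_shape = input_shape,
    predict = function(batch) {
      p <- matrix(1e-6, length(batch), n_classes)
      p[, k] <- 1
      p / rowSums(p)
    },
    name = sprintf("const%d", k))
}
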
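test_that("band datasets are balanced, bounded, and bit-reproducible", {
  spec <- band_dataset_spec(n_classes = 3, images_per_class = 12,
                            size = c(16, 16), seed = 4)
  d1 <- make_band_dataset(spec)
  d2 <- make_band_dataset(spec)
  expect_identical(d1$images, d2$images)
  expect_identical(d1$labels, d2$labels)
  expect_equal(as.vector(table(d1$labels)), rep(12, 3))
  expect_true(all(vapply(d1$images, function(im) all(im >= 0 & im <= 1),
                         logical(1))))
  expect_error(make_band_dataset(band_dataset_spec(
    n_classes = 2, images_per_class = 2, size = c(8, 8),
    class_bands = rbind(c(0.01, 0.02), c(0.5, 1)))), "no frequency bins")
})

test_that("class templates concentrate their power inside the class band", {
  ds <- make_band_dataset(band_dataset_spec(n_classes = 4,
                                            images_per_class = 2, seed = 5))
  for (k in 1:4) {
    sp <- power_spectrum(ds$templates[[k]], "nyquist")
    inband <- sp$grid$radius >= ds$spec$class_bands[k, 1] - 1e-9 &
      sp$grid$radius <= ds$spec$class_bands[k, 2] + 1e-9
    expect_gt(sum(sp$values[inband]) / sum(sp$values), 0.9)
  }
})

test_that("amplitude decay weights template atoms by radial frequency", {
  spec <- band_dataset_spec(n_classes = 2, images_per_class = 2,
                            class_bands = matrix(rep(c(0.1, 1.2), each = 2),
                                                 ncol = 2),
                            amplitude_decay = 1, seed = 6)
  ds <- make_band_dataset(spec)
  sp <- power_spectrum(ds$templates[[1]], "nyquist")
  lo <- sp$grid$radius > 0 & sp$grid$radius <= 0.4
  hi <- sp$grid$radius > 0.8
  expect_gt(sum(sp$values[lo]), sum(sp$values[hi]))
})

test_that("cue signatures and amplitude jitter shape samples as documented", {
  spec <- band_dataset_spec(n_classes = 2, images_per_class = 6,
                            class_bands = matrix(rep(c(0.1, 0.3), each = 2),
                                                 ncol = 2),
                            template_components = 4, amplitude_jitter = 0.5,
                            cue_band = c(0.7, 0.9), cue_components = 3,
                            cue_amplitude = 0.2, seed = 9)
  d1 <- make_band_dataset(spec)
  expect_identical(d1$images, make_band_dataset(spec)$images)
  # templates carry energy in both the main band and the cue band
  sp <- power_spectrum(d1$templates[[1]], "nyquist")
  main <- sp$grid$radius >= 0.1 - 1e-9 & sp$grid$radius <= 0.3 + 1e-9
  cue <- sp$grid$radius >= 0.7 - 1e-9 & sp$grid$radius <= 0.9 + 1e-9
  expect_gt(sum(sp$values[main]), 0)
  expect_gt(sum(sp$values[cue]), 0)
  expect_gt(sum(sp$values[main]), sum(sp$values[cue]))
})

test_that("the band-template oracle is perfect on clean samples", {
  spec <- band_dataset_spec(n_classes = 4, images_per_class = 15,
                            noise_std = 0, seed = 5)
  ds <- make_band_dataset(spec)
  orc <- make_oracle_classifier(ds, cutoff = sqrt(2))
  pred <- max.col(orc$predict(ds$images), ties.method = "first")
  expect_equal(mean(pred == ds$labels), 1)
  # full-band cutoff equals a full-band spectral correlation classifier
  orc2 <- make_oracle_classifier(ds, cutoff = 10)
  expect_equal(orc$predict(ds$images[1:5]), orc2$predict(ds$images[1:5]))
  expect_error(make_oracle_classifier(list(ds$templates[[1]],
                                           ds$templates[[1]]), 0.5),
               "identical")
})

test_that("tiny CNN reaches high accuracy on an easy two-class problem", {
  ds <- make_band_dataset(band_dataset_spec(
    n_classes = 2, images_per_class = 100, size = c(16, 16),
    class_bands = rbind(c(0.15, 0.4), c(0.7, 0.95)), noise_std = 0.02,
    seed = 7))
  split <- split_dataset(ds)
  m <- train_tiny_cnn(split$train, epochs = 10, seed = 1)
  expect_true(attr(m, "converged"))
  acc <- mean(max.col(m$predict(split$test$images)) == split$test$labels)
  expect_gte(acc, 0.95)
})

test_that("tiny CNN training is reproducible given the seed", {
  ds <- make_band_dataset(band_dataset_spec(
    n_classes = 2, images_per_class = 30, size = c(16, 16),
    class_bands = rbind(c(0.15, 0.4), c(0.7, 0.95)), seed = 8))
  m1 <- train_tiny_cnn(ds, epochs = 3, seed = 9)
  m2 <- train_tiny_cnn(ds, epochs = 3, seed = 9)
  probe <- ds$images[1:10]
  expect_identical(m1$predict(probe), m2$predict(probe))
})

test_that("tiny CNN warns rather than silently failing to converge", {
  # pure-noise labels cannot be learned
  set.seed(10)
  junk <- list(images = lapply(1:40, function(i) rand_image(16, 16, i)),
               labels = rep(1:4, 10))
  expect_warning(train_tiny_cnn(junk, epochs = 1, seed = 1),
                 "did not converge")
})

test_that("tiny CNN input gradients match finite differences", {
  ds <- make_band_dataset(band_dataset_spec(
    n_classes = 2, images_per_class = 20, size = c(12, 12),
    class_bands = rbind(c(0.2, 0.5), c(0.7, 1.0)), seed = 11))
  m <- train_tiny_cnn(ds, epochs = 3, seed = 2, ksize = 5L)
  x <- ds$images[[1]]
  g <- m$loss_gradient(x, 2)
  fd <- x * 0
  lp <- function(z) -log(m$predict(list(z))[1, 2])
  for (i in seq_along(x)) {
    e <- x * 0; e[i] <- 1e-5
    fd[i] <- (lp(x + e) - lp(x - e)) / 2e-5
  }
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-3)
})

test_that("grayscale conversion uses fixed weights and is idempotent", {
  arr <- array(stats::runif(48), dim = c(4, 4, 3))
  g <- to_grayscale(arr)
  expect_equal(g, 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3])
  expect_identical(to_grayscale(g), g)
})

test_that("naturalistic images have a decaying isotropic spectrum", {
  imgs <- make_naturalistic_images(20, size = c(32, 32), seed = 3)
  expect_true(all(vapply(imgs, function(im) all(im >= 0.1499 & im <= 0.8501),
                         logical(1))))
  fh <- half_power_frequency(lapply(imgs, function(im) im - mean(im)))$f_half
  # much redder than white noise
  expect_lt(fh, 0.6 * brute_flat_fhalf(32, 32, "sampling"))
})

test_that("synthetic V1 responses have the requested noise level", {
  stim <- make_naturalistic_images(120, size = c(16, 16), seed = 4)
  v1 <- make_synthetic_v1(stim, n_neurons = 90, rf_band = c(0.05, 0.3),
                          noise_std = 0.2, seed = 5)
  # >10^4 response draws; mean per-neuron noise/signal sd ratio within 10%
  ratio <- mean(apply(v1$responses - v1$signal, 2, stats::sd) /
                  apply(v1$signal, 2, stats::sd))
  expect_equal(ratio, 0.2, tolerance = 0.1)
  # noiseless responses equal exact inner products
  v0 <- make_synthetic_v1(stim[1:5], n_neurons = 3, noise_std = 0, seed = 6)
  manual <- sum(v0$filters[[2]] * stim[[3]])
  expect_equal(v0$responses[3, 2], manual, tolerance = 1e-10)
})
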
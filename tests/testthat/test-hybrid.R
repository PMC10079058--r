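test_that("low-pass mask covers exactly the bins inside the cutoff", {
  m0 <- lowpass_mask(8, 8, 0)
  expect_equal(sum(m0$values), 1)
  expect_equal(m0$grid$radius[m0$values == 1], 0)
  expect_equal(sum(lowpass_mask(8, 8, sqrt(2))$values), 64)
  # brute-force count on 32x32 at f_mix = 0.5
  m <- lowpass_mask(32, 32, 0.5)
  expect_equal(sum(m$values),
               sum(brute_bin_radii(32, 32, "nyquist") <= 0.5 + 1e-12))
  expect_error(lowpass_mask(8, 8, -0.1), "nonnegative")
})

test_that("hybrid construction obeys the self-mix and full-mask identities", {
  x <- rand_image(16, 16, 1)
  for (fm in c(0, 0.4, 0.9)) {
    expect_lt(max(abs(make_hybrid(x, x, fm)$pixels - x)), 1e-6)
  }
  y <- rand_image(16, 16, 2)
  expect_lt(max(abs(make_hybrid(x, y, sqrt(2))$pixels - x)), 1e-12)
  expect_error(make_hybrid(x, rand_image(8, 8, 3), 0.5), "shape")
})

test_that("hybrid spectra split exactly along the mask (Parseval split)", {
  set.seed(4)
  for (rep in 1:10) {
    lo <- rand_image(16, 16, rep)
    hi <- rand_image(16, 16, rep + 100)
    for (fm in c(0.2, 0.6, 1.0)) {
      h <- make_hybrid(lo, hi, fm)
      sh <- power_spectrum(h$pixels, "nyquist")
      sl <- power_spectrum(lo, "nyquist")
      su <- power_spectrum(hi, "nyquist")
      m <- lowpass_mask(16, 16, fm)$values == 1
      expect_equal(sum(sh$values[m]), sum(sl$values[m]),
                   tolerance = 1e-6)
      expect_equal(sum(sh$values[!m]), sum(su$values[!m]),
                   tolerance = 1e-6)
    }
  }
})

test_that("rgb hybrids apply the same mask per channel", {
  lo <- array(stats::runif(16 * 16 * 3), dim = c(16, 16, 3))
  hi <- array(stats::runif(16 * 16 * 3), dim = c(16, 16, 3))
  h <- make_hybrid(lo, hi, 0.5)
  for (c in 1:3) {
    hc <- make_hybrid(lo[, , c], hi[, , c], 0.5)
    expect_equal(h$pixels[, , c], hc$pixels, tolerance = 1e-12)
  }
})

test_that("hybrid dataset sampling is deterministic, valid and uniform", {
  imgs <- lapply(1:40, function(i) rand_image(8, 8, i))
  labs <- rep(1:4, each = 10)
  d1 <- build_hybrid_dataset(imgs, labs, n_pairs = 30, seed = 7)
  d2 <- build_hybrid_dataset(imgs, labs, n_pairs = 30, seed = 7)
  expect_identical(d1$pairs, d2$pairs)
  expect_identical(d1$hybrids[[3]][[5]]$pixels, d2$hybrids[[3]][[5]]$pixels)
  expect_true(all(d1$pairs$low_label != d1$pairs$high_label))
  expect_error(build_hybrid_dataset(imgs, rep(1, 40), n_pairs = 5), "two classes")
  # class-pair distribution uniform over the 12 ordered unequal pairs
  big <- build_hybrid_dataset(imgs, labs, f_mix_grid = 0.5, n_pairs = 1200,
                              seed = 0)
  counts <- table(paste(big$pairs$low_label, big$pairs$high_label))
  expect_equal(length(counts), 12L)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("probing a constant model gives degenerate probabilities", {
  imgs <- lapply(1:20, function(i) rand_image(8, 8, i))
  labs <- rep(1:2, each = 10)
  ds <- build_hybrid_dataset(imgs, labs, f_mix_grid = c(0.2, 0.8),
                             n_pairs = 20, seed = 1)
  # force every low seed to class 1 by filtering pairs
  keep <- ds$pairs$low_label == 1
  flat <- unlist(ds$hybrids, recursive = FALSE)[rep(keep, 2)]
  pc <- probe_classifier(constant_model(1, 2, c(8, 8)), flat)
  expect_true(all(pc$p_low == 1))
  expect_true(all(pc$p_high == 0))
})

test_that("swapping seeds under the complementary mask mirrors the curve", {
  # A (x) M + B (x) (1-M) is the swapped pair mixed through the complement
  # of M, so relabeling low<->high on the same pixels must mirror the curve
  ds <- make_band_dataset(band_dataset_spec(n_classes = 3, images_per_class = 8,
                                            size = c(16, 16), seed = 3))
  orc <- make_oracle_classifier(ds, cutoff = sqrt(2))
  set.seed(5)
  fgrid <- c(0.3, 0.7, 1.1)
  i <- sample(which(ds$labels == 1), 3); j <- sample(which(ds$labels == 2), 3)
  hs <- sw <- list()
  for (r in 1:3) {
    for (f in fgrid) {
      h <- make_hybrid(ds$images[[i[r]]], ds$images[[j[r]]], f,
                       low_label = 1L, high_label = 2L)
      h2 <- h
      h2$low_label <- 2L; h2$high_label <- 1L
      hs[[length(hs) + 1L]] <- h
      sw[[length(sw) + 1L]] <- h2
    }
  }
  a <- probe_classifier(orc, hs)
  b <- probe_classifier(orc, sw)
  expect_equal(a$p_low, b$p_high)
  expect_equal(a$p_high, b$p_low)
})

test_that("reversal frequency interpolates the first sign change", {
  f <- seq(0, 1, length.out = 11)
  curve <- structure(list(f_mix = f, p_low = (2 * f - 1 + 1) / 2,
                          p_high = 1 - (2 * f - 1 + 1) / 2,
                          n_images = rep(10, 11), statistic = "top1"),
                     class = "probe_curve")
  # d(f) = 2f - 1 crosses zero at exactly 0.5
  rv <- reversal_frequency(curve)
  expect_equal(rv$f_rev, 0.5, tolerance = 1e-12)
  expect_equal(rv$censored, "none")
  # never-positive difference is censored, not fabricated
  curve$p_low <- rep(0.1, 11); curve$p_high <- rep(0.6, 11)
  rv2 <- reversal_frequency(curve)
  expect_true(is.na(rv2$f_rev))
  expect_equal(rv2$censored, "right")
  # positive from the start is left-censored at the first grid point
  curve$p_low <- rep(0.8, 11); curve$p_high <- rep(0.1, 11)
  rv3 <- reversal_frequency(curve)
  expect_equal(rv3$f_rev, 0)
  expect_equal(rv3$censored, "left")
})

test_that("oracle probe crossing matches per-pair energy bookkeeping", {
  ds <- make_band_dataset(band_dataset_spec(n_classes = 4,
                                            images_per_class = 20, seed = 11))
  hd <- build_hybrid_dataset(ds$images, ds$labels, n_pairs = 50, seed = 2)
  for (cutoff in c(0.5, 0.8)) {
    orc <- make_oracle_classifier(ds, cutoff = cutoff)
    est <- reversal_frequency(probe_classifier(orc, hd))$f_rev
    bc <- brute_oracle_curve(ds$images, ds$templates, hd$pairs,
                             hd$f_mix_grid, cutoff)
    pred <- brute_crossing(bc$f_mix, bc$p_low - bc$p_high)
    expect_lt(abs(est - pred), 0.05)
  }
})

test_that("doubling the f_mix grid moves f_rev less than the coarse spacing", {
  ds <- make_band_dataset(band_dataset_spec(n_classes = 4,
                                            images_per_class = 20, seed = 13))
  orc <- make_oracle_classifier(ds, cutoff = 0.6)
  coarse_grid <- seq(0, sqrt(2), length.out = 9)
  fine_grid <- seq(0, sqrt(2), length.out = 17)
  coarse <- build_hybrid_dataset(ds$images, ds$labels, coarse_grid,
                                 n_pairs = 60, seed = 4)
  fine <- build_hybrid_dataset(ds$images, ds$labels, fine_grid,
                               n_pairs = 60, seed = 4)
  f1 <- reversal_frequency(probe_classifier(orc, coarse))$f_rev
  f2 <- reversal_frequency(probe_classifier(orc, fine))$f_rev
  expect_lt(abs(f1 - f2), diff(coarse_grid)[1])
})
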
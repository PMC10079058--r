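# Generators for every synthetic input the pipeline needs: band-structured
# image classes (a stand-in for "low-frequency shape vs high-frequency
# texture" content in natural datasets, with derivable ground truth), oracle
# classifiers with known frequency preference, linear models with closed-form
# attack margins, 1/f naturalistic images, and V1-like response matrices.

#' Specification of a band-structured synthetic dataset
#'
#' Each class is a fixed template: a sum of on-grid sinusoidal atoms whose
#' radial frequencies lie inside the class band (Nyquist units), so class-
#' discriminative content occupies a controlled frequency band. Samples are
#' random circular translations of the template plus white noise, affinely
#' rescaled to `[0, 1]`.
#'
#' @param n_classes Number of classes.
#' @param images_per_class Samples per class.
#' @param size `c(H, W)`.
#' @param channels 1 (grayscale) or 3.
#' @param class_bands n_classes x 2 matrix of `(f_lo, f_hi)` in Nyquist
#'   units, `0 <= f_lo < f_hi <= sqrt(2)`. Default: contiguous equal-width
#'   bands spanning `[0.1, 1.1]`.
#' @param template_components Sinusoidal atoms per class template.
#' @param amplitude_decay Spectral decay exponent: an atom at radial
#'   frequency r gets amplitude `(r0 / r)^amplitude_decay` with `r0` the
#'   lowest band edge in use. 0 (default) gives equal-amplitude atoms;
#'   1 mimics the 1/f amplitude falloff of natural images, making
#'   high-frequency class evidence weak the way it is in photographs.
#' @param amplitude_jitter Lognormal sd of per-sample multiplicative jitter
#'   on the template atom amplitudes (0 = none). Jitter makes the main
#'   template band a noisier class cue, the way object appearance varies
#'   while fine texture statistics stay stable.
#' @param cue_band Optional `(f_lo, f_hi)` band for a small-amplitude
#'   per-class signature: a second set of atoms, exact in every sample,
#'   that carries crisp but low-energy class evidence (natural images pair
#'   strong variable low-frequency structure with faint reliable
#'   high-frequency texture cues). `NULL` (default) disables it.
#' @param cue_components Atoms in the signature.
#' @param cue_amplitude Amplitude of each signature atom relative to the
#'   main atoms' base amplitude.
#' @param noise_std Pixel noise standard deviation (template peak is O(1)).
#' @param seed Integer seed; the dataset is a pure function of this spec.
#' @return A `band_dataset_spec`.
#' @export
band_dataset_spec <- function(n_classes = 4L, images_per_class = 500L,
                              size = c(32L, 32L), channels = 1L,
                              class_bands = NULL, template_components = 8L,
                              amplitude_decay = 0, amplitude_jitter = 0,
                              cue_band = NULL, cue_components = 0L,
                              cue_amplitude = 0.1, noise_std = 0.05,
                              seed = 0L) {
  n_classes <- as.integer(n_classes)
  if (is.null(class_bands)) {
    edges <- seq(0.1, 1.1, length.out = n_classes + 1L)
    class_bands <- cbind(edges[-(n_classes + 1L)], edges[-1L])
  }
  class_bands <- matrix(as.numeric(class_bands), ncol = 2L)
  stopifnot(nrow(class_bands) == n_classes,
            all(class_bands[, 1L] >= 0), all(class_bands[, 2L] <= sqrt(2)),
            all(class_bands[, 1L] < class_bands[, 2L]),
            channels %in% c(1L, 3L))
  structure(list(n_classes = n_classes,
                 images_per_class = as.integer(images_per_class),
                 size = as.integer(size), channels = as.integer(channels),
                 class_bands = class_bands,
                 template_components = as.integer(template_components),
                 amplitude_decay = amplitude_decay,
                 amplitude_jitter = amplitude_jitter,
                 cue_band = cue_band, cue_components = as.integer(cue_components),
                 cue_amplitude = cue_amplitude,
                 noise_std = noise_std, seed = as.integer(seed)),
            class = "band_dataset_spec")
}

# integer frequency bins (ky, kx) whose Nyquist radius lies inside [lo, hi]
band_bins <- function(h, w, lo, hi) {
  kx <- seq(-floor(w / 2), ceiling(w / 2) - 1L)
  ky <- seq(-floor(h / 2), ceiling(h / 2) - 1L)
  g <- expand.grid(ky = ky, kx = kx)
  r <- 2 * sqrt((g$kx / w)^2 + (g$ky / h)^2)
  keep <- r >= lo & r <= hi & !(g$kx == 0 & g$ky == 0)
  g[keep, , drop = FALSE]
}

# evaluate a sum of on-grid cosine atoms, optionally circularly shifted
atoms_image <- function(atoms, h, w, dy = 0, dx = 0) {
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ys <- matrix(0:(h - 1), h, w)
  img <- matrix(0, h, w)
  amp <- if (is.null(atoms$amp)) rep(1, nrow(atoms)) else atoms$amp
  for (a in seq_len(nrow(atoms))) {
    img <- img + amp[a] * cos(2 * pi * (atoms$kx[a] * (xs + dx) / w +
                                        atoms$ky[a] * (ys + dy) / h) + atoms$phase[a])
  }
  img
}

#' Generate a band-structured labeled image dataset
#'
#' @param spec A `band_dataset_spec` (or arguments forwarded to it).
#' @param ... Passed to [band_dataset_spec()] when `spec` is missing.
#' @return A `band_dataset`: `images` (list of matrices/arrays in `[0, 1]`),
#'   `labels` (integer, balanced), `templates` (one per class, unscaled), and
#'   the `spec`.
#' @export
make_band_dataset <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- band_dataset_spec(...)
  stopifnot(inherits(spec, "band_dataset_spec"))
  h <- spec$size[1L]; w <- spec$size[2L]
  with_seed(spec$seed, {
    templates <- vector("list", spec$n_classes)
    atom_sets <- vector("list", spec$n_classes)
    for (k in seq_len(spec$n_classes)) {
      bins <- band_bins(h, w, spec$class_bands[k, 1L], spec$class_bands[k, 2L])
      if (nrow(bins) == 0L) {
        stop(sprintf("class %d band [%.2f, %.2f] contains no frequency bins",
                     k, spec$class_bands[k, 1L], spec$class_bands[k, 2L]))
      }
      pick <- bins[sample.int(nrow(bins), min(spec$template_components, nrow(bins))), ]
      pick$phase <- stats::runif(nrow(pick), 0, 2 * pi)
      r <- 2 * sqrt((pick$kx / w)^2 + (pick$ky / h)^2)
      r0 <- max(min(spec$class_bands[, 1L]), 2 / max(h, w))
      pick$amp <- (r0 / pmax(r, r0))^spec$amplitude_decay
      pick$jitter <- TRUE
      if (!is.null(spec$cue_band) && spec$cue_components > 0L) {
        cbins <- band_bins(h, w, spec$cue_band[1L], spec$cue_band[2L])
        if (nrow(cbins) == 0L) stop("cue band contains no frequency bins")
        cue <- cbins[sample.int(nrow(cbins),
                                min(spec$cue_components, nrow(cbins))), ]
        cue$phase <- stats::runif(nrow(cue), 0, 2 * pi)
        cue$amp <- spec$cue_amplitude
        cue$jitter <- FALSE
        pick <- rbind(pick, cue)
      }
      atom_sets[[k]] <- pick
      templates[[k]] <- atoms_image(pick, h, w)
    }
    n <- spec$n_classes * spec$images_per_class
    labels <- rep(seq_len(spec$n_classes), each = spec$images_per_class)
    images <- vector("list", n)
    for (i in seq_len(n)) {
      k <- labels[i]
      dy <- sample.int(h, 1L) - 1L
      dx <- sample.int(w, 1L) - 1L
      atoms <- atom_sets[[k]]
      if (spec$amplitude_jitter > 0) {
        jit <- exp(stats::rnorm(nrow(atoms), 0, spec$amplitude_jitter))
        atoms$amp <- atoms$amp * ifelse(atoms$jitter, jit, 1)
      }
      img <- atoms_image(atoms, h, w, dy = dy, dx = dx) +
        matrix(stats::rnorm(h * w, 0, spec$noise_std *
                              max(1, stats::sd(templates[[k]]))), h, w)
      rng <- range(img)
      img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0 + 0.5
      if (spec$channels == 3L) img <- array(rep(img, 3L), dim = c(h, w, 3L))
      images[[i]] <- img
    }
    structure(list(images = images, labels = labels, templates = templates,
                   spec = spec),
              class = "band_dataset")
  })
}

#' @export
print.band_dataset <- function(x, ...) {
  cat(sprintf("<band_dataset> %d images (%d classes x %d), %dx%d, seed %d\n",
              length(x$images), x$spec$n_classes, x$spec$images_per_class,
              x$spec$size[1L], x$spec$size[2L], x$spec$seed))
  invisible(x)
}

# amplitude spectrum feature used by the oracle: centered |DFT| of the
# luminance channel, DC zeroed, restricted to radius <= cutoff
oracle_feature <- function(image, cutoff) {
  sp <- power_spectrum(to_grayscale(image), mode = "nyquist")
  a <- sqrt(sp$values)
  a[sp$grid$radius == 0] <- 0
  a[sp$grid$radius > cutoff + 1e-12] <- 0
  a[a < 1e-9 * max(a)] <- 0   # drop float residue so empty bands stay empty
  a
}

#' Band-template oracle classifier
#'
#' A probe-only classifier with analytically derivable frequency preference:
#' it low-passes the input at `cutoff` (Nyquist units) and predicts the class
#' whose template has the most similar content there. Similarity is the
#' cosine between low-passed amplitude spectra (DC excluded), which is
#' invariant to the translations, phase shifts and affine rescaling used by
#' the sample generator -- so clean, noiseless samples are classified
#' perfectly by construction, and the oracle's response to any hybrid pair
#' can be predicted exactly from band-energy bookkeeping on the two seeds.
#'
#' @param gallery A `band_dataset` (its templates are used) or a list of
#'   class template images.
#' @param cutoff Low-pass cutoff in Nyquist units; `sqrt(2)` makes the
#'   oracle a full-band spectral correlation classifier.
#' @param temperature Softmax temperature on the cosine scores.
#' @return A `classifier_handle` (no gradient).
#' @export
make_oracle_classifier <- function(gallery, cutoff, temperature = 20) {
  templates <- if (inherits(gallery, "band_dataset")) gallery$templates else gallery
  stopifnot(is.list(templates), length(templates) >= 2L, cutoff >= 0)
  for (i in seq_along(templates)) {
    for (j in seq_len(i - 1L)) {
      if (max(abs(templates[[i]] - templates[[j]])) < 1e-12) {
        stop("degenerate gallery: identical class templates")
      }
    }
  }
  tf <- lapply(templates, oracle_feature, cutoff = cutoff)
  tn <- lapply(tf, function(v) {
    nv <- sqrt(sum(v^2))
    if (nv > 0) v / nv else v
  })
  K <- length(tn)
  d0 <- dim(templates[[1L]])
  predict_fun <- function(batch) {
    scores <- t(vapply(batch, function(img) {
      a <- oracle_feature(img, cutoff)
      na <- sqrt(sum(a^2))
      if (na == 0) return(rep(0, K))
      vapply(tn, function(tv) sum(a * tv) / na, numeric(1))
    }, numeric(K)))
    ex <- exp(temperature * (scores - apply(scores, 1L, max)))
    ex / rowSums(ex)
  }
  classifier_handle(n_classes = K, input_shape = d0, predict = predict_fun,
                    name = sprintf("band_oracle(cutoff=%.3g)", cutoff))
}

#' Linear softmax classifier with closed-form attack margins
#'
#' Class scores `W x + b` on the flattened image, softmax probabilities, and
#' the exact input gradient of the targeted cross-entropy. For two classes
#' the minimal targeted L-infinity perturbation has the closed form
#' `margin / ||w_t - w_o||_1`, which makes this the reference model for
#' attack-oracle tests.
#'
#' @param W K x N weight matrix (one row per class).
#' @param b Length-K bias.
#' @param input_shape Image shape `c(H, W)` or `c(H, W, C)` with product N.
#' @return A `classifier_handle` with gradient support.
#' @export
make_linear_classifier <- function(W, b, input_shape) {
  W <- as.matrix(W)
  stopifnot(length(b) == nrow(W), prod(input_shape) == ncol(W))
  softmax_rows <- function(L) {
    ex <- exp(L - apply(L, 1L, max))
    ex / rowSums(ex)
  }
  classifier_handle(
    n_classes = nrow(W), input_shape = input_shape,
    predict = function(batch) {
      X <- t(vapply(batch, as.vector, numeric(ncol(W))))
      softmax_rows(X %*% t(W) + matrix(b, nrow(X), length(b), byrow = TRUE))
    },
    loss_gradient = function(image, target) {
      x <- as.vector(image)
      p <- softmax_rows(matrix(W %*% x + b, 1L))
      e <- rep(0, nrow(W)); e[target] <- 1
      g <- as.vector(t(W) %*% (as.vector(p) - e))
      out <- image; out[] <- g
      out
    },
    name = "linear_softmax"
  )
}

#' 1/f naturalistic random images
#'
#' Random-phase fields with isotropic amplitude spectrum `1/||f||^exponent`
#' (the characteristic spectral falloff of natural images), affinely mapped
#' into `range`. Used as reference images for corruption-spectrum checks.
#'
#' @param n Number of images.
#' @param size `c(H, W)`.
#' @param exponent Amplitude spectral exponent (1 gives 1/f amplitude).
#' @param seed Integer seed.
#' @param range Output pixel range (kept away from 0/1 so additive
#'   corruptions do not clip).
#' @return List of H x W matrices.
#' @export
make_naturalistic_images <- function(n, size = c(32L, 32L), exponent = 1,
                                     seed = 0L, range = c(0.15, 0.85)) {
  h <- size[1L]; w <- size[2L]
  g <- frequency_grid(h, w, "sampling")
  amp <- 1 / pmax(g$radius, min(1 / h, 1 / w))^exponent
  amp <- ifftshift2(amp)
  with_seed(seed, lapply(seq_len(n), function(i) {
    z <- matrix(stats::rnorm(h * w), h, w)
    f <- Re(stats::fft(stats::fft(z) * amp, inverse = TRUE)) / (h * w)
    rng <- base::range(f)
    range[1L] + (f - rng[1L]) / (rng[2L] - rng[1L]) * diff(range)
  }))
}

#' Synthetic V1-like response set
#'
#' Emulates a population whose dominant dimensions are linear receptive
#' fields with low spatial frequency: neuron j responds
#' `<g_j, x> + noise`, with `g_j` a random Gabor whose carrier radial
#' frequency lies in `rf_band` (Nyquist units). The noise standard deviation
#' is `noise_std` times the per-neuron signal standard deviation, and the
#' ground-truth filters plus noiseless signal are stored for recovery tests.
#'
#' @param stimuli List of stimulus images (identical shapes; luminance is
#'   used for color stimuli).
#' @param n_neurons Number of neurons.
#' @param rf_band `(f_lo, f_hi)` carrier band in Nyquist units.
#' @param noise_std Noise-to-signal ratio (sd units).
#' @param seed Integer seed.
#' @return A `neural_response_set`: `responses` (stimuli x neurons),
#'   `stimulus_images`, `filters` (list of Gabor images), `signal`
#'   (noiseless responses), `noise_std`.
#' @export
make_synthetic_v1 <- function(stimuli, n_neurons, rf_band = c(0.05, 0.3),
                              noise_std = 0.1, seed = 0L) {
  stopifnot(n_neurons >= 1, length(stimuli) >= 1)
  gray <- lapply(stimuli, to_grayscale)
  h <- nrow(gray[[1L]]); w <- ncol(gray[[1L]])
  with_seed(seed, {
    sigma <- min(h, w) / 5   # wide enough for a tight spectrum, little border truncation
    xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
    ys <- matrix(0:(h - 1), h, w)
    filters <- lapply(seq_len(n_neurons), function(j) {
      fr <- stats::runif(1, rf_band[1L], rf_band[2L]) / 2   # cycles/pixel
      th <- stats::runif(1, 0, pi)
      ph <- stats::runif(1, 0, 2 * pi)
      cx <- stats::runif(1, 0.4, 0.6) * w
      cy <- stats::runif(1, 0.4, 0.6) * h
      env <- exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigma^2))
      env * cos(2 * pi * fr * ((xs - cx) * cos(th) + (ys - cy) * sin(th)) + ph)
    })
    G <- vapply(filters, as.vector, numeric(h * w))          # pixels x neurons
    S <- t(vapply(gray, as.vector, numeric(h * w)))          # stimuli x pixels
    signal <- S %*% G
    sds <- apply(signal, 2L, stats::sd)
    sds[sds == 0] <- 1
    noise <- matrix(stats::rnorm(length(signal)), nrow(signal)) *
      matrix(noise_std * sds, nrow(signal), ncol(signal), byrow = TRUE)
    structure(list(responses = signal + noise, stimulus_images = stimuli,
                   filters = filters, signal = signal, noise_std = noise_std,
                   rf_band = rf_band, seed = as.integer(seed)),
              class = "neural_response_set")
  })
}

#' @export
print.neural_response_set <- function(x, ...) {
  cat(sprintf("<neural_response_set> %d stimuli x %d neurons, rf band [%.2f, %.2f]\n",
              nrow(x$responses), ncol(x$responses), x$rf_band[1L], x$rf_band[2L]))
  invisible(x)
}
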
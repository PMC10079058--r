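# Hybrid images: low-frequency content of one seed image combined with the
# high-frequency content of another through a radial binary mask, then probed
# against a classifier to estimate the reversal frequency f_rev.

#' Radial binary low-pass mask
#'
#' Indicator of Fourier bins whose radial frequency satisfies
#' `||f|| <= f_mix`, on the fftshift-centered grid in Nyquist units (the
#' convention used for hybrid mixing). Point-symmetric about DC, so masked
#' spectra of real images stay conjugate-symmetric.
#'
#' @param height,width Mask size in bins.
#' @param f_mix Cutoff radius in Nyquist units, >= 0. Values >= sqrt(2) cover
#'   the whole grid.
#' @return A `lowpass_mask` object with binary `values` and its `freq_grid`.
#' @export
lowpass_mask <- function(height, width, f_mix) {
  if (!is.numeric(f_mix) || length(f_mix) != 1L || f_mix < 0) {
    stop("`f_mix` must be a single nonnegative number")
  }
  grid <- frequency_grid(height, width, "nyquist")
  vals <- (grid$radius <= f_mix + 1e-12) * 1
  structure(list(grid = grid, f_mix = f_mix, values = vals),
            class = "lowpass_mask")
}

#' Construct a hybrid image
#'
#' Combines the Fourier components of `low` below `f_mix` with the components
#' of `high` above it: the hybrid spectrum is
#' `F_low * M + F_high * (1 - M)` with `M` the radial binary mask, inverted
#' back to pixel space. The real part is returned after checking that the
#' imaginary residue is numerically negligible. No clipping is applied, so the
#' construction stays exactly linear in its two seeds (PNG export clips
#' separately).
#'
#' @param low,high Seed images of identical shape; `low` contributes the
#'   low-frequency band. RGB images are mixed with the same mask per channel.
#' @param f_mix Cutoff in Nyquist units.
#' @param low_label,high_label Optional class ids carried along for probing.
#' @param low_seed_id,high_seed_id Optional dataset indices (provenance).
#' @return A `hybrid_image` with fields `pixels`, `f_mix`, labels and ids.
#' @export
make_hybrid <- function(low, high, f_mix,
                        low_label = NA_integer_, high_label = NA_integer_,
                        low_seed_id = NA_integer_, high_seed_id = NA_integer_) {
  check_image(low, "low"); check_image(high, "high")
  if (!identical(dim(low), dim(high))) stop("seed images differ in shape")
  h <- nrow(low); w <- ncol(low)
  m <- ifftshift2(lowpass_mask(h, w, f_mix)$values)
  lc <- image_channels(low); hc <- image_channels(high)
  out <- vector("list", length(lc))
  for (k in seq_along(lc)) {
    fh <- stats::fft(lc[[k]]) * m + stats::fft(hc[[k]]) * (1 - m)
    x <- stats::fft(fh, inverse = TRUE) / (h * w)
    if (max(abs(Im(x))) > 1e-8 * max(1, max(abs(Re(x))))) {
      stop("unexpected imaginary residue in inverse transform")
    }
    out[[k]] <- Re(x)
  }
  structure(
    list(pixels = channels_to_image(out, low), f_mix = f_mix,
         low_label = low_label, high_label = high_label,
         low_seed_id = low_seed_id, high_seed_id = high_seed_id),
    class = "hybrid_image"
  )
}

#' Build a hybrid-image probe dataset
#'
#' Draws `n_pairs` seed pairs uniformly at random with the two seeds from
#' different classes, then mixes every pair at every value of `f_mix_grid`.
#' The same pair list is reused across all mixing frequencies, so probe
#' curves are paired comparisons that differ only in the mask. Deterministic
#' given `seed`.
#'
#' @param images List of images (identical shapes).
#' @param labels Integer class labels, one per image; >= 2 classes required.
#' @param f_mix_grid Sorted mixing frequencies in Nyquist units. Default: 17
#'   evenly spaced values spanning `[0, sqrt(2)]`.
#' @param n_pairs Number of seed pairs.
#' @param seed Integer seed controlling pair sampling.
#' @return A `hybrid_dataset`: `pairs` (data frame with seed ids and labels),
#'   `f_mix_grid`, and `hybrids`, a list (over f_mix) of lists of
#'   `hybrid_image` objects.
#' @export
build_hybrid_dataset <- function(images, labels,
                                 f_mix_grid = seq(0, sqrt(2), length.out = 17),
                                 n_pairs = 100L, seed = 0L) {
  stopifnot(is.list(images), length(images) == length(labels), n_pairs >= 1)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("need at least two classes to build hybrid pairs")
  }
  f_mix_grid <- sort(f_mix_grid)
  pairs <- with_seed(seed, {
    low_id <- sample.int(length(images), n_pairs, replace = TRUE)
    high_id <- vapply(low_id, function(i) {
      cand <- which(labels != labels[i])
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    data.frame(low_id = low_id, high_id = high_id,
               low_label = labels[low_id], high_label = labels[high_id])
  })
  hybrids <- lapply(f_mix_grid, function(fm) {
    lapply(seq_len(n_pairs), function(j) {
      make_hybrid(images[[pairs$low_id[j]]], images[[pairs$high_id[j]]], fm,
                  low_label = pairs$low_label[j],
                  high_label = pairs$high_label[j],
                  low_seed_id = pairs$low_id[j],
                  high_seed_id = pairs$high_id[j])
    })
  })
  structure(list(pairs = pairs, f_mix_grid = f_mix_grid, hybrids = hybrids),
            class = "hybrid_dataset")
}

#' Probe a classifier with hybrid images
#'
#' For each mixing frequency, computes `p_low` (fraction of hybrids whose
#' top-1 prediction equals the low-frequency seed's class) and `p_high`
#' (analogous for the high-frequency seed). Ties in the top-1 are broken by
#' the lowest class id. A softmax-mass variant (`statistic = "softmax"`) uses
#' the mean probability mass assigned to each seed class instead of
#' indicator frequencies.
#'
#' @param model A `classifier_handle`.
#' @param dataset A `hybrid_dataset` (or a flat list of `hybrid_image`s).
#' @param statistic `"top1"` (default) or `"softmax"`.
#' @return A `probe_curve`: `f_mix`, `p_low`, `p_high`, `n_images`.
#' @export
probe_classifier <- function(model, dataset, statistic = c("top1", "softmax")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(model, "classifier_handle"))
  if (inherits(dataset, "hybrid_dataset")) {
    groups <- dataset$hybrids
    fgrid <- dataset$f_mix_grid
  } else {
    fm <- vapply(dataset, function(h) h$f_mix, numeric(1))
    fgrid <- sort(unique(fm))
    groups <- lapply(fgrid, function(f) dataset[fm == f])
  }
  p_low <- p_high <- n_img <- numeric(length(fgrid))
  for (i in seq_along(fgrid)) {
    hs <- groups[[i]]
    probs <- tryCatch(
      model$predict(lapply(hs, function(h) h$pixels)),
      error = function(e) stop(sprintf("model failed on batch %d (f_mix = %.3f): %s",
                                       i, fgrid[i], conditionMessage(e)))
    )
    lo <- vapply(hs, function(h) h$low_label, integer(1))
    hi <- vapply(hs, function(h) h$high_label, integer(1))
    if (statistic == "top1") {
      pred <- max.col(probs, ties.method = "first")
      p_low[i] <- mean(pred == lo)
      p_high[i] <- mean(pred == hi)
    } else {
      p_low[i] <- mean(probs[cbind(seq_len(nrow(probs)), lo)])
      p_high[i] <- mean(probs[cbind(seq_len(nrow(probs)), hi)])
    }
    n_img[i] <- length(hs)
  }
  structure(list(f_mix = fgrid, p_low = p_low, p_high = p_high,
                 n_images = n_img, statistic = statistic),
            class = "probe_curve")
}

#' Reversal frequency of a probe curve
#'
#' f_rev is the mixing frequency where `p_low = p_high`: the first crossing
#' of `d(f) = p_low - p_high` from <= 0 to > 0, located by linear
#' interpolation between the bracketing grid points. If the difference curve
#' starts positive the estimate is left-censored at the first grid point; if
#' it never becomes positive the estimate is censored (NA) and flagged -- no
#' number is fabricated.
#'
#' @param curve A `probe_curve` with >= 2 grid points.
#' @return List with `f_rev` (NA when censored) and `censored` flag
#'   (`"none"`, `"left"`, or `"right"`).
#' @export
reversal_frequency <- function(curve) {
  stopifnot(inherits(curve, "probe_curve"), length(curve$f_mix) >= 2L)
  d <- curve$p_low - curve$p_high
  k <- which(d > 0)[1L]
  if (is.na(k)) {
    return(list(f_rev = NA_real_, censored = "right"))
  }
  if (k == 1L) {
    return(list(f_rev = curve$f_mix[1L], censored = "left"))
  }
  x0 <- curve$f_mix[k - 1L]; x1 <- curve$f_mix[k]
  y0 <- d[k - 1L]; y1 <- d[k]
  list(f_rev = x0 + (0 - y0) / (y1 - y0) * (x1 - x0), censored = "none")
}

#' Reversal frequency with permutation spread
#'
#' Regenerates the hybrid pairing `n_permutations` times (fresh random seed
#' pairs each time, same mixing grid), probes the model on each dataset, and
#' reports the mean and standard deviation of the per-permutation reversal
#' frequencies -- the uncertainty convention of randomly permuted hybrid
#' datasets.
#'
#' @inheritParams build_hybrid_dataset
#' @param model A `classifier_handle`.
#' @param n_permutations Number of regenerated pairings (default 4).
#' @param statistic Passed to [probe_classifier()].
#' @return List with `f_rev` (mean over permutations), `spread` (sd),
#'   `per_permutation` values, and the list of `curves`.
#' @export
probe_reversal <- function(model, images, labels,
                           f_mix_grid = seq(0, sqrt(2), length.out = 17),
                           n_pairs = 100L, n_permutations = 4L, seed = 0L,
                           statistic = "top1") {
  vals <- numeric(n_permutations)
  curves <- vector("list", n_permutations)
  for (p in seq_len(n_permutations)) {
    ds <- build_hybrid_dataset(images, labels, f_mix_grid, n_pairs,
                               seed = seed + p - 1L)
    curves[[p]] <- probe_classifier(model, ds, statistic)
    rv <- reversal_frequency(curves[[p]])
    vals[p] <- rv$f_rev
  }
  list(f_rev = mean(vals), spread = if (n_permutations > 1L) stats::sd(vals) else 0,
       per_permutation = vals, curves = curves)
}

#' @export
print.probe_curve <- function(x, ...) {
  cat(sprintf("<probe_curve> %d f_mix points (%s), n = %d per point\n",
              length(x$f_mix), x$statistic, x$n_images[1L]))
  invisible(x)
}

#' Plot a probe curve
#'
#' @param x A `probe_curve`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.probe_curve <- function(x, ...) {
  graphics::matplot(x$f_mix, cbind(x$p_low, x$p_high), type = "b", pch = c(1, 2),
                    lty = 1, col = c("steelblue", "tomato"),
                    xlab = "mixing frequency (Nyquist units)",
                    ylab = "probability", ...)
  graphics::legend("right", c("p_low", "p_high"), pch = c(1, 2),
                   col = c("steelblue", "tomato"), bty = "n")
  rv <- reversal_frequency(x)
  if (rv$censored == "none") graphics::abline(v = rv$f_rev, lty = 2)
  invisible(x)
}
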
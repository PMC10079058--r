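# Fourier utilities: centered power spectra, spectrum averaging, radial
# profiles, and the half-power frequency statistic f_0.5.

#' Centered 2-D frequency grid
#'
#' Builds the fftshift-centered frequency coordinates of an H x W discrete
#' Fourier transform. Two normalizations are supported and always labeled:
#' \describe{
#'   \item{sampling}{frequencies in cycles/pixel, i.e. normalized by the
#'     sampling frequency; axis range [-0.5, 0.5).}
#'   \item{nyquist}{normalized by the Nyquist frequency (half the sampling
#'     frequency); axis range [-1, 1). Radii are exactly twice the
#'     sampling-mode radii.}
#' }
#' The zero-frequency (DC) bin sits at index `(floor(H/2)+1, floor(W/2)+1)`.
#'
#' @param height,width Grid size in bins.
#' @param mode `"sampling"` or `"nyquist"`.
#' @return A `freq_grid` object with matrices `fx`, `fy`, `radius`
#'   (`radius = sqrt(fx^2 + fy^2)`).
#' @export
frequency_grid <- function(height, width, mode = c("sampling", "nyquist")) {
  mode <- match.arg(mode)
  stopifnot(height >= 1, width >= 1)
  scale <- if (mode == "nyquist") 2 else 1
  f1 <- function(n) {
    k <- 0:(n - 1)
    k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
    (k / n)[shift_idx(n)] * scale
  }
  fyv <- f1(height)
  fxv <- f1(width)
  fx <- matrix(fxv, nrow = height, ncol = width, byrow = TRUE)
  fy <- matrix(fyv, nrow = height, ncol = width)
  structure(
    list(height = as.integer(height), width = as.integer(width),
         mode = mode, fx = fx, fy = fy, radius = sqrt(fx^2 + fy^2)),
    class = "freq_grid"
  )
}

#' Centered power spectrum of an image
#'
#' Squared magnitude of the unnormalized 2-D DFT, fftshift-centered so DC is
#' at the grid center. Multi-channel images are handled per channel and the
#' channel spectra averaged. With the unnormalized DFT convention the total
#' power obeys Parseval's identity: `sum(values) = H * W * sum(pixel^2)`.
#'
#' @param image H x W matrix or H x W x C array with finite values.
#' @param mode Frequency normalization of the attached grid.
#' @param kind `"power"` (squared magnitude, the default used throughout) or
#'   `"amplitude"` (magnitude).
#' @return A `power_spectrum` object: `values` (H x W, nonnegative), `grid`,
#'   and `n_averaged = 1`.
#' @export
power_spectrum <- function(image, mode = c("sampling", "nyquist"),
                           kind = c("power", "amplitude")) {
  mode <- match.arg(mode)
  kind <- match.arg(kind)
  check_image(image)
  chans <- image_channels(image)
  acc <- NULL
  for (ch in chans) {
    p <- Mod(stats::fft(ch))
    if (kind == "power") p <- p^2
    acc <- if (is.null(acc)) p else acc + p
  }
  vals <- fftshift2(acc / length(chans))
  structure(
    list(values = vals,
         grid = frequency_grid(nrow(vals), ncol(vals), mode),
         n_averaged = 1L, kind = kind),
    class = "power_spectrum"
  )
}

#' Average the power spectra of a set of images
#'
#' Arithmetic mean of per-image centered power spectra, as used when
#' averaging the spectra of many minimal adversarial perturbations.
#'
#' @param images Nonempty list of images, all the same shape.
#' @inheritParams power_spectrum
#' @return A `power_spectrum` with `n_averaged = length(images)`.
#' @export
mean_spectrum <- function(images, mode = c("sampling", "nyquist"),
                          kind = c("power", "amplitude")) {
  mode <- match.arg(mode)
  kind <- match.arg(kind)
  if (!is.list(images) || length(images) == 0L) {
    stop("`images` must be a nonempty list")
  }
  d0 <- dim(images[[1L]])
  acc <- NULL
  for (i in seq_along(images)) {
    if (!identical(dim(images[[i]]), d0)) {
      stop(sprintf("image %d has a different shape", i))
    }
    s <- power_spectrum(images[[i]], mode, kind)
    acc <- if (is.null(acc)) s$values else acc + s$values
  }
  structure(
    list(values = acc / length(images),
         grid = frequency_grid(nrow(acc), ncol(acc), mode),
         n_averaged = length(images), kind = kind),
    class = "power_spectrum"
  )
}

#' Cumulative radial profile of a power spectrum
#'
#' For each distinct radial frequency r on the grid, the fraction of total
#' spectral power carried by bins with radius <= r. The DC bin enters at
#' r = 0. The half-power frequency `f_half` is the smallest distinct radius
#' at which the cumulative fraction reaches 0.5 (a right-continuous
#' quantile, so a pure tone at radius r gives `f_half = r` exactly and a
#' DC-dominant spectrum gives `f_half = 0`).
#'
#' @param spectrum A `power_spectrum` with positive total power.
#' @return A `radial_profile` object: `radii`, `cum_fraction`, `f_half`, and
#'   the grid `mode`.
#' @export
radial_profile <- function(spectrum) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  total <- sum(spectrum$values)
  if (!(total > 0)) stop("all-zero spectrum: radial profile undefined")
  r <- signif(as.vector(spectrum$grid$radius), 12)
  p <- as.vector(spectrum$values)
  agg <- rowsum(p, group = r)          # sorted by unique radius
  radii <- as.numeric(rownames(agg))
  cf <- cumsum(agg[, 1L]) / total
  f_half <- radii[which(cf >= 0.5)[1L]]
  structure(
    list(radii = radii, cum_fraction = as.numeric(cf), f_half = f_half,
         mode = spectrum$grid$mode),
    class = "radial_profile"
  )
}

# first upward crossing of `level` on a nondecreasing curve, linear
# interpolation between adjacent points; 0-th point handled per contract
half_crossing <- function(x, y, level) {
  i <- which(y >= level)[1L]
  if (is.na(i)) return(x[length(x)])
  if (i == 1L) return(x[1L])
  x[i - 1L] + (level - y[i - 1L]) / (y[i] - y[i - 1L]) * (x[i] - x[i - 1L])
}

#' Half-power frequency of a set of images or perturbations
#'
#' f_0.5 is the radial frequency below which half of the Fourier power lies.
#' The point estimate is the f_half of the mean spectrum of the set; the
#' spread is the standard deviation of per-image f_half values.
#'
#' @param images Nonempty list of images (e.g. minimal adversarial
#'   perturbations), all the same shape.
#' @param mode Frequency normalization (`"sampling"` matches the perturbation
#'   spectra convention; `"nyquist"` the hybrid-image convention).
#' @return List with `f_half`, `spread`, `n`, `mode`, and
#'   `spread_method = "per_image_sd"`.
#' @export
half_power_frequency <- function(images, mode = c("sampling", "nyquist")) {
  mode <- match.arg(mode)
  if (!is.list(images) || length(images) == 0L) {
    stop("`images` must be a nonempty list")
  }
  per <- vapply(images, function(im) {
    radial_profile(power_spectrum(im, mode))$f_half
  }, numeric(1))
  f <- radial_profile(mean_spectrum(images, mode))$f_half
  list(f_half = f,
       spread = if (length(per) > 1L) stats::sd(per) else 0,
       n = length(images), mode = mode, spread_method = "per_image_sd")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %d radii (%s mode), f_half = %.4f\n",
              length(x$radii), x$mode, x$f_half))
  invisible(x)
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d x %d (%s mode, %s), n_averaged = %d\n",
              x$grid$height, x$grid$width, x$grid$mode, x$kind, x$n_averaged))
  invisible(x)
}

#' Plot a cumulative radial profile
#'
#' @param x A `radial_profile`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.radial_profile <- function(x, ...) {
  graphics::plot(x$radii, x$cum_fraction, type = "s",
                 xlab = sprintf("radial frequency (%s units)", x$mode),
                 ylab = "cumulative power fraction", ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey40")
  graphics::abline(v = x$f_half, lty = 2, col = "firebrick")
  invisible(x)
}
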
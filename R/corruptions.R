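# Procedural common-corruption suite with 5 severity levels and the
# low/mid/high frequency grouping. The families follow the common-corruption
# benchmark taxonomy; the per-severity parameterizations are this package's
# own and are documented in `corruption_params()`. Weather corruptions carry
# a "_like" suffix: they are parameterized low-frequency overlays whose
# defining property (low-frequency difference spectrum) is tested, not
# assumed.

.corruption_groups <- c(
  gaussian_noise = "high", shot_noise = "high", impulse_noise = "high",
  defocus_blur = "mid", motion_blur = "mid", pixelate = "mid",
  jpeg_compression = "mid", elastic_transform = "mid",
  brightness = "low", contrast = "low",
  fog_like = "low", snow_like = "low", frost_like = "low"
)

.corruption_params <- list(
  gaussian_noise   = list(sd = c(0.04, 0.07, 0.10, 0.14, 0.19)),
  shot_noise       = list(photons = c(250, 120, 60, 30, 15)),
  impulse_noise    = list(p = c(0.01, 0.03, 0.06, 0.10, 0.15)),
  defocus_blur     = list(radius = c(1, 1.5, 2, 2.5, 3)),
  motion_blur      = list(len = c(3, 5, 7, 9, 11)),
  pixelate         = list(block = c(2, 3, 4, 6, 8)),
  jpeg_compression = list(step = c(0.04, 0.08, 0.15, 0.28, 0.45)),
  elastic_transform = list(alpha = c(0.8, 1.5, 2.2, 3.0, 4.0), smooth = 4),
  brightness       = list(offset = c(0.05, 0.10, 0.15, 0.22, 0.30)),
  contrast         = list(factor = c(0.75, 0.60, 0.45, 0.30, 0.20)),
  fog_like         = list(t = c(0.10, 0.20, 0.30, 0.42, 0.55)),
  snow_like        = list(amount = c(0.08, 0.15, 0.22, 0.32, 0.45)),
  frost_like       = list(t = c(0.15, 0.25, 0.38, 0.50, 0.65))
)

#' Names of the built-in corruption families
#' @return Character vector of the 13 family names.
#' @export
corruption_names <- function() names(.corruption_groups)

#' Per-severity parameter tables of the corruption suite
#' @return Named list, one entry per family, each a list of per-severity
#'   parameter vectors (index = severity).
#' @export
corruption_params <- function() .corruption_params

#' Frequency group of a corruption family
#'
#' The fixed low/mid/high grouping by spectral content of the corruption's
#' difference image: noise families are high-frequency; blur, pixelation,
#' compression and warping are mid; global intensity changes and weather-like
#' overlays are low.
#'
#' @param name Corruption family name (bare weather names `fog`, `snow`,
#'   `frost` are accepted as aliases of the `_like` implementations).
#' @return `"low"`, `"mid"`, or `"high"`.
#' @export
frequency_group <- function(name) {
  alias <- c(fog = "fog_like", snow = "snow_like", frost = "frost_like")
  if (name %in% names(alias)) name <- alias[[name]]
  if (!name %in% names(.corruption_groups)) {
    stop(sprintf("unknown corruption '%s'", name))
  }
  unname(.corruption_groups[[name]])
}

#' Corruption specification
#'
#' @param name Family name (see [corruption_names()]).
#' @param severity Integer 1..5 (0 is the identity, the clean limit).
#' @param seed Seed controlling any stochastic component.
#' @return A `corruption_spec` with the resolved `group` and `params`.
#' @export
corruption_spec <- function(name, severity, seed = 0L) {
  group <- frequency_group(name)   # validates the name
  alias <- c(fog = "fog_like", snow = "snow_like", frost = "frost_like")
  if (name %in% names(alias)) name <- alias[[name]]
  severity <- as.integer(severity)
  if (severity < 0L || severity > 5L) stop("severity must be in 0..5")
  params <- if (severity == 0L) list() else {
    lapply(.corruption_params[[name]], function(v) {
      if (length(v) == 5L) v[severity] else v
    })
  }
  structure(list(name = name, severity = severity, group = group,
                 params = params, seed = as.integer(seed)),
            class = "corruption_spec")
}

#' Full corruption suite
#'
#' @param names Families to include (default all 13).
#' @param severities Severity levels (default 1:5).
#' @param seed Base seed; each spec gets a distinct derived seed.
#' @return List of `corruption_spec`s.
#' @export
corruption_suite <- function(names = corruption_names(), severities = 1:5,
                             seed = 0L) {
  out <- list()
  k <- 0L
  for (nm in names) for (sv in severities) {
    k <- k + 1L
    out[[k]] <- corruption_spec(nm, sv, seed = seed + k)
  }
  out
}

# replicate a single-channel field across the channels of `like`
bcast <- function(m, like) {
  if (length(dim(like)) == 2L) m else array(m, dim = dim(like))
}

# zero-mean unit-sd random field with a Gaussian low-pass spectral envelope
lowpass_field <- function(h, w, cutoff = 0.08) {
  z <- matrix(stats::rnorm(h * w), h, w)
  g <- frequency_grid(h, w, "sampling")
  env <- ifftshift2(exp(-(g$radius / cutoff)^2))
  f <- Re(stats::fft(stats::fft(z) * env, inverse = TRUE)) / (h * w)
  (f - mean(f)) / stats::sd(f)
}

conv_reflect <- function(x, w) {
  r <- (nrow(w) - 1L) %/% 2L
  chans <- lapply(image_channels(x), function(ch) conv_valid(pad_reflect(ch, r), w))
  channels_to_image(chans, x)
}

disk_kernel <- function(radius) {
  r <- ceiling(radius)
  d <- seq(-r, r)
  dist <- sqrt(outer(d^2, d^2, "+"))
  w <- pmin(pmax(radius + 0.5 - dist, 0), 1)   # soft-edged disk
  w / sum(w)
}

motion_kernel <- function(len) {
  w <- diag(1, len, len)                        # 45-degree streak
  w / sum(w)
}

dct_mat <- function(n = 8L) {
  x <- 0:(n - 1)
  C <- sqrt(2 / n) * cos(outer(x, 2 * x + 1) * pi / (2 * n))
  C[1, ] <- sqrt(1 / n)
  C
}

jpeg_channel <- function(ch, step) {
  C <- dct_mat(8L)
  h <- nrow(ch); w <- ncol(ch)
  hp <- 8L * ceiling(h / 8L); wp <- 8L * ceiling(w / 8L)
  xp <- rbind(ch, ch[rev(seq_len(hp - h)), , drop = FALSE])
  xp <- cbind(xp, xp[, rev(seq_len(wp - w)), drop = FALSE])
  u <- 0:7
  q <- step * (1 + outer(u, u, "+") / 4)        # coarser at high frequency
  for (bi in seq_len(hp / 8L)) {
    for (bj in seq_len(wp / 8L)) {
      ri <- (8L * (bi - 1L) + 1L):(8L * bi)
      ci <- (8L * (bj - 1L) + 1L):(8L * bj)
      Y <- C %*% xp[ri, ci] %*% t(C)
      xp[ri, ci] <- t(C) %*% (q * round(Y / q)) %*% C
    }
  }
  xp[1:h, 1:w]
}

bilinear_sample <- function(ch, si, sj) {
  h <- nrow(ch); w <- ncol(ch)
  si <- pmin(pmax(as.vector(si), 1), h); sj <- pmin(pmax(as.vector(sj), 1), w)
  i0 <- floor(si); j0 <- floor(sj)
  i1 <- pmin(i0 + 1, h); j1 <- pmin(j0 + 1, w)
  ti <- si - i0; tj <- sj - j0
  v00 <- ch[cbind(i0, j0)]; v01 <- ch[cbind(i0, j1)]
  v10 <- ch[cbind(i1, j0)]; v11 <- ch[cbind(i1, j1)]
  out <- (1 - ti) * ((1 - tj) * v00 + tj * v01) + ti * ((1 - tj) * v10 + tj * v11)
  matrix(out, h, w)
}

#' Apply a corruption to an image
#'
#' Produces the corrupted image clipped to `[0, 1]`. Stochastic families are
#' bit-deterministic given `spec$seed`. Severity 0 is the identity.
#'
#' @param image Image with values in `[0, 1]`.
#' @param spec A `corruption_spec`.
#' @return Corrupted image of the same shape.
#' @export
apply_corruption <- function(image, spec) {
  stopifnot(inherits(spec, "corruption_spec"))
  check_image(image)
  if (spec$severity == 0L) return(clip01(image))
  p <- spec$params
  h <- nrow(image); w <- ncol(image)
  out <- switch(spec$name,
    gaussian_noise = with_seed(spec$seed,
      image + array(stats::rnorm(length(image), 0, p$sd), dim = dim(image))),
    shot_noise = with_seed(spec$seed, {
      x <- clip01(image)
      array(stats::rpois(length(x), as.vector(x) * p$photons) / p$photons,
            dim = dim(image))
    }),
    impulse_noise = with_seed(spec$seed, {
      n <- length(image)
      hit <- stats::runif(n) < p$p
      val <- stats::runif(n) < 0.5
      x <- as.vector(image)
      x[hit] <- as.numeric(val[hit])
      array(x, dim = dim(image))
    }),
    defocus_blur = conv_reflect(image, disk_kernel(p$radius)),
    motion_blur = conv_reflect(image, motion_kernel(p$len)),
    pixelate = {
      gi <- ceiling(seq_len(h) / p$block)
      gj <- ceiling(seq_len(w) / p$block)
      chans <- lapply(image_channels(image), function(ch) {
        bm <- rowsum(ch, gi) / as.vector(table(gi))
        bm <- t(rowsum(t(bm), gj) / as.vector(table(gj)))
        bm[gi, gj, drop = FALSE]
      })
      channels_to_image(chans, image)
    },
    jpeg_compression = {
      chans <- lapply(image_channels(image), jpeg_channel, step = p$step)
      channels_to_image(chans, image)
    },
    elastic_transform = with_seed(spec$seed, {
      # displacement fields smoothed with a Gaussian of sd `smooth` pixels,
      # applied spectrally so small images are handled too
      cutoff <- 1 / (2 * pi * p$smooth)
      di <- p$alpha * lowpass_field(h, w, cutoff)
      dj <- p$alpha * lowpass_field(h, w, cutoff)
      ii <- matrix(seq_len(h), h, w) + di
      jj <- matrix(seq_len(w), h, w, byrow = TRUE) + dj
      chans <- lapply(image_channels(image), bilinear_sample, si = ii, sj = jj)
      channels_to_image(chans, image)
    }),
    brightness = image + p$offset,
    contrast = mean(image) + p$factor * (image - mean(image)),
    fog_like = with_seed(spec$seed, {
      f01 <- stats::pnorm(lowpass_field(h, w))  # low-frequency haze in [0,1]
      (1 - p$t) * image + p$t * bcast(0.6 + 0.4 * f01, image)
    }),
    snow_like = with_seed(spec$seed, {
      f <- lowpass_field(h, w, cutoff = 0.12)
      overlay <- pmax(f - 1, 0)                 # sparse bright low-freq patches
      image + p$amount * 2 * bcast(overlay, image)
    }),
    frost_like = with_seed(spec$seed, {
      f01 <- stats::pnorm(lowpass_field(h, w, cutoff = 0.1))
      image * (1 - p$t * bcast(f01, image))
    }),
    stop(sprintf("unknown corruption '%s'", spec$name))
  )
  clip01(out)
}

#' Radial profile of a corruption's difference spectrum
#'
#' Applies the corruption to each reference image (stochastic draws vary per
#' reference), averages the power spectra of the difference images
#' `corrupted - clean`, and returns the cumulative radial profile -- the
#' consistency check behind the frequency grouping.
#'
#' @param spec A `corruption_spec`.
#' @param references Nonempty list of clean images.
#' @param mode Frequency normalization (default `"sampling"`).
#' @return A `radial_profile` of the mean difference spectrum.
#' @export
corruption_spectrum <- function(spec, references,
                                mode = c("sampling", "nyquist")) {
  mode <- match.arg(mode)
  stopifnot(length(references) > 0L)
  diffs <- lapply(seq_along(references), function(i) {
    sp <- spec
    sp$seed <- spec$seed + i - 1L
    apply_corruption(references[[i]], sp) - clip01(references[[i]])
  })
  radial_profile(mean_spectrum(diffs, mode))
}
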
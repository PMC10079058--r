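# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's spectral/hybrid code paths: grids, shifts and spectra
# are recomputed from first principles.

# direct O(N^2) double-loop 2-D DFT power (unnormalized convention)
brute_dft_power <- function(x) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (u in 0:(h - 1)) {
    for (v in 0:(w - 1)) {
      s <- 0 + 0i
      for (i in 0:(h - 1)) {
        for (j in 0:(w - 1)) {
          s <- s + x[i + 1, j + 1] * exp(-2i * pi * (u * i / h + v * j / w))
        }
      }
      out[u + 1, v + 1] <- Mod(s)^2
    }
  }
  out
}

# centered radial frequencies by enumeration: vector of the H*W bin radii
brute_bin_radii <- function(h, w, mode = "sampling") {
  scale <- if (mode == "nyquist") 2 else 1
  fr <- function(k, n) ifelse(k >= ceiling(n / 2), k - n, k) / n
  r <- numeric(0)
  for (u in 0:(h - 1)) {
    for (v in 0:(w - 1)) {
      r <- c(r, sqrt(fr(u, h)^2 + fr(v, w)^2) * scale)
    }
  }
  r
}

# half-power radius of a flat spectrum: smallest distinct radius at which
# the cumulative bin-count fraction reaches one half (the median bin radius)
brute_flat_fhalf <- function(h, w, mode = "sampling") {
  r <- sort(brute_bin_radii(h, w, mode))
  ur <- unique(signif(r, 12))
  cf <- vapply(ur, function(x) mean(r <= x + 1e-12), numeric(1))
  ur[which(cf >= 0.5)[1]]
}

# --- band-template oracle bookkeeping --------------------------------------
# Predicts the band-template oracle's response to every hybrid pair at every
# mixing frequency purely from the seed images' spectra (no hybrid image is
# ever formed), then aggregates the p_low/p_high curve and locates the
# crossing. Mirrors the oracle's scoring rule by construction.

brute_amp_spectrum <- function(img) {
  if (length(dim(img)) == 3L) {
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  Mod(stats::fft(img))   # uncentered; radii computed uncentered below
}

brute_uncentered_radius <- function(h, w) {
  fr <- function(k, n) ifelse(k >= ceiling(n / 2), k - n, k) / n
  fy <- matrix(fr(0:(h - 1), h), h, w)
  fx <- matrix(fr(0:(w - 1), w), h, w, byrow = TRUE)
  2 * sqrt(fx^2 + fy^2)   # nyquist units
}

brute_oracle_feature <- function(amp, rad, cutoff) {
  a <- amp
  a[rad == 0] <- 0
  a[rad > cutoff + 1e-12] <- 0
  a[a < 1e-9 * max(a)] <- 0
  a
}

# probe curve predicted by bookkeeping for given pairs over f_mix_grid
brute_oracle_curve <- function(images, templates, pairs, f_mix_grid, cutoff) {
  h <- nrow(templates[[1]]); w <- ncol(templates[[1]])
  rad <- brute_uncentered_radius(h, w)
  tfeat <- lapply(templates, function(tp) {
    v <- brute_oracle_feature(brute_amp_spectrum(tp), rad, cutoff)
    n <- sqrt(sum(v^2)); if (n > 0) v / n else v
  })
  amps <- lapply(images, brute_amp_spectrum)
  K <- length(templates)
  p_low <- p_high <- numeric(length(f_mix_grid))
  for (fi in seq_along(f_mix_grid)) {
    m <- rad <= f_mix_grid[fi] + 1e-12
    pred <- integer(nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      ahyb <- amps[[pairs$low_id[p]]] * m + amps[[pairs$high_id[p]]] * (1 - m)
      a <- brute_oracle_feature(ahyb, rad, cutoff)
      na <- sqrt(sum(a^2))
      sc <- if (na == 0) rep(0, K) else
        vapply(tfeat, function(tv) sum(a * tv) / na, numeric(1))
      pred[p] <- which.max(sc)   # ties -> lowest class id
    }
    p_low[fi] <- mean(pred == pairs$low_label)
    p_high[fi] <- mean(pred == pairs$high_label)
  }
  list(f_mix = f_mix_grid, p_low = p_low, p_high = p_high)
}

brute_crossing <- function(f, d) {
  k <- which(d > 0)[1]
  if (is.na(k)) return(NA_real_)
  if (k == 1) return(f[1])
  f[k - 1] + (0 - d[k - 1]) / (d[k] - d[k - 1]) * (f[k] - f[k - 1])
}

# closed-form minimal targeted L-inf perturbation for a 2-class linear model
brute_linear_margin <- function(W, b, x, cur, tgt) {
  as.numeric(((W[cur, ] - W[tgt, ]) %*% x + b[cur] - b[tgt]) /
               sum(abs(W[tgt, ] - W[cur, ])))
}
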
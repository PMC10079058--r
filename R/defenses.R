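# Fixed-weight preprocessing defenses: Gaussian blur and PCA projection.
# Both are linear, and both expose an exact adjoint so input gradients can be
# chained through them for gradient-based attacks.

#' Normalized Gaussian convolution kernel
#'
#' Isotropic kernel `w(dx, dy) = exp(-(dx^2 + dy^2) / (2 sigma^2)) / Z` on a
#' square support of half-width `radius = ceiling(3 * sigma)` (>= 99.7% of
#' the continuous mass), with `Z` chosen so the weights sum to 1.
#'
#' @param sigma Standard deviation in pixels, > 0.
#' @return A `gaussian_kernel`: `sigma`, `radius`, `weights`
#'   ((2r+1) x (2r+1)), `Z`.
#' @export
gaussian_kernel <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a single positive number")
  }
  r <- as.integer(ceiling(3 * sigma))
  d <- seq(-r, r)
  un <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  Z <- sum(un)
  structure(list(sigma = sigma, radius = r, weights = un / Z, Z = Z),
            class = "gaussian_kernel")
}

# reflect (no edge duplication) index map for length n, pad r; needs r <= n-1
reflect_idx <- function(n, r) {
  p <- seq_len(n + 2L * r) - r
  p[p < 1L] <- 2L - p[p < 1L]
  p[p > n] <- 2L * n - p[p > n]
  p
}

pad_reflect <- function(x, r) {
  x[reflect_idx(nrow(x), r), reflect_idx(ncol(x), r), drop = FALSE]
}

# valid 2-D convolution of a padded image with a (2r+1)^2 kernel
conv_valid <- function(xpad, w) {
  k <- nrow(w)
  H <- nrow(xpad) - k + 1L
  W <- ncol(xpad) - k + 1L
  out <- matrix(0, H, W)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (w[i, j] == 0) next
      out <- out + w[i, j] * xpad[i:(i + H - 1L), j:(j + W - 1L)]
    }
  }
  out
}

blur_channel <- function(x, kern) {
  r <- kern$radius
  if (nrow(x) < 2L * r + 1L || ncol(x) < 2L * r + 1L) {
    stop("image smaller than the blur kernel support")
  }
  conv_valid(pad_reflect(x, r), kern$weights)
}

# exact adjoint of blur_channel: transpose of (valid conv) o (reflect pad)
blur_channel_adjoint <- function(g, kern) {
  r <- kern$radius
  H <- nrow(g); W <- ncol(g)
  k <- 2L * r + 1L
  gpad <- matrix(0, H + 2L * r, W + 2L * r)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      w <- kern$weights[i, j]
      if (w == 0) next
      gpad[i:(i + H - 1L), j:(j + W - 1L)] <-
        gpad[i:(i + H - 1L), j:(j + W - 1L)] + w * g
    }
  }
  ri <- reflect_idx(H, r); ci <- reflect_idx(W, r)
  lin <- outer(ri, (ci - 1L) * H, "+")   # linear source index per padded bin
  out <- rowsum(as.vector(gpad), group = as.vector(lin))
  matrix(out[, 1L], H, W)
}

#' Blur an image with a fixed Gaussian kernel
#'
#' Per-channel 2-D convolution with reflect padding (mirrored borders, edge
#' pixel not repeated), output the same shape as the input. The operation is
#' linear in the input, so gradients pass through it exactly (see
#' [blur_defense()] for the adjoint used in attack chains).
#'
#' @param image Image, each spatial dimension at least the kernel support.
#' @param kernel A `gaussian_kernel` (default `sigma = 1.5`, the package's
#'   standard blur defense strength).
#' @return Blurred image of the same shape.
#' @export
blur_preprocess <- function(image, kernel = gaussian_kernel(1.5)) {
  check_image(image)
  stopifnot(inherits(kernel, "gaussian_kernel"))
  chans <- lapply(image_channels(image), blur_channel, kern = kernel)
  channels_to_image(chans, image)
}

#' Fit a PCA basis on training images
#'
#' Flattens each image to a length-N vector (column-major, channels last),
#' subtracts the empirical mean, and takes the top-K eigenvectors of the
#' empirical covariance (via SVD of the centered data matrix). Eigenvalues
#' use the (n-1) divisor. Component signs are fixed deterministically: the
#' largest-magnitude entry of each component is positive.
#'
#' @param train_images List of images of identical shape; must contain at
#'   least K linearly independent examples.
#' @param K Number of retained components, `1 <= K <= N`.
#' @return A `pca_basis`: `mean` (length N), `components` (N x K,
#'   orthonormal columns), `eigenvalues` (length K, nonincreasing), `N`, `K`,
#'   and the image `shape`.
#' @export
fit_pca <- function(train_images, K) {
  stopifnot(is.list(train_images), length(train_images) >= 2L, K >= 1)
  d0 <- dim(train_images[[1L]])
  X <- t(vapply(train_images, function(im) {
    check_image(im)
    if (!identical(dim(im), d0)) stop("training images differ in shape")
    as.vector(im)
  }, numeric(prod(d0))))
  N <- ncol(X)
  if (K > N) stop("K exceeds the pixel count N")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0, nv = min(nrow(X), N))
  avail <- sum(sv$d > max(sv$d) * 1e-10)
  if (K > avail) {
    stop(sprintf("only %d linearly independent directions available, K = %d", avail, K))
  }
  V <- sv$v[, seq_len(K), drop = FALSE]
  for (j in seq_len(K)) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  structure(list(mean = mu, components = V,
                 eigenvalues = sv$d[seq_len(K)]^2 / (nrow(X) - 1L),
                 all_eigenvalues = sv$d^2 / (nrow(X) - 1L),
                 N = N, K = as.integer(K), shape = d0),
            class = "pca_basis")
}

#' Project an image onto the retained PCA subspace
#'
#' Computes `x_hat = P (x - mean) + mean` with `P = V V^T` the orthogonal
#' projector onto the span of the top-K components: the image is denoised by
#' removing everything outside the leading principal subspace. Idempotent;
#' the identity when K = N. Linear in the input (after centering), so
#' gradients chain through exactly.
#'
#' @param image Image whose pixel count equals the basis dimension N.
#' @param basis A `pca_basis`.
#' @return Image of the same shape.
#' @export
pca_preprocess <- function(image, basis) {
  check_image(image)
  stopifnot(inherits(basis, "pca_basis"))
  x <- as.vector(image)
  if (length(x) != basis$N) stop("image pixel count does not match the basis")
  xc <- x - basis$mean
  xh <- basis$mean + as.vector(basis$components %*% crossprod(basis$components, xc))
  out <- image
  out[] <- xh
  out
}

#' Blur defense object
#'
#' Packages the Gaussian blur as a `defense` with a `forward` map and its
#' exact `adjoint`, ready for [compose()].
#'
#' @param sigma Kernel standard deviation in pixels (default 1.5).
#' @return A `defense` object.
#' @export
blur_defense <- function(sigma = 1.5) {
  kern <- gaussian_kernel(sigma)
  structure(list(
    name = sprintf("blur(sigma=%.3g)", sigma),
    params = list(sigma = sigma, kernel = kern),
    forward = function(x) blur_preprocess(x, kern),
    adjoint = function(g) {
      chans <- lapply(image_channels(g), blur_channel_adjoint, kern = kern)
      channels_to_image(chans, g)
    }
  ), class = "defense")
}

#' PCA defense object
#'
#' Packages the PCA projection as a `defense` with `forward` and exact
#' `adjoint` (the projector is symmetric).
#'
#' @param basis A `pca_basis` from [fit_pca()].
#' @return A `defense` object.
#' @export
pca_defense <- function(basis) {
  stopifnot(inherits(basis, "pca_basis"))
  structure(list(
    name = sprintf("pca(K=%d)", basis$K),
    params = list(basis = basis),
    forward = function(x) pca_preprocess(x, basis),
    adjoint = function(g) {
      gv <- as.vector(g)
      out <- g
      out[] <- as.vector(basis$components %*% crossprod(basis$components, gv))
      out
    }
  ), class = "defense")
}

#' Identity defense (no preprocessing)
#'
#' @return A `defense` object whose forward and adjoint are the identity.
#' @export
identity_defense <- function() {
  structure(list(name = "identity", params = list(),
                 forward = function(x) x, adjoint = function(g) g),
            class = "defense")
}

#' Compose a preprocessing defense with a classifier
#'
#' Returns a new `classifier_handle` whose probabilities are
#' `model$predict(preprocess(x))` and whose input-gradient is the chain-rule
#' composition `adjoint(grad of model at preprocess(x))`. Passing `NULL` or
#' the identity defense returns predictions bit-identical to the bare model.
#'
#' @param preprocess A `defense` (or `NULL` for identity).
#' @param model A `classifier_handle`.
#' @return A composed `classifier_handle`.
#' @export
compose <- function(preprocess, model) {
  stopifnot(inherits(model, "classifier_handle"))
  if (is.null(preprocess)) return(model)
  stopifnot(inherits(preprocess, "defense"))
  grad_fun <- if (is.null(model$loss_gradient)) NULL else function(image, target) {
    g <- model$loss_gradient(preprocess$forward(image), target)
    preprocess$adjoint(g)
  }
  classifier_handle(
    n_classes = model$n_classes,
    input_shape = model$input_shape,
    predict = function(batch) model$predict(lapply(batch, preprocess$forward)),
    loss_gradient = grad_fun,
    name = paste0(preprocess$name, " + ", model$name)
  )
}
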
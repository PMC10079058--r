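# Tiny trainable convolutional classifier: the desk-scale stand-in for the
# deep networks probed in the full-scale experiments. One convolutional
# layer, quadratic activation, log mean-pooled energy features, softmax
# head. Written from scratch so exact input gradients (needed by PGD) come
# from the same hand-derived backward pass as the weight gradients.

# im2col linear indices for valid convolution: npos x k^2 matrix of indices
# into a column-major H x W image
im2col_idx <- function(h, w, k) {
  oi <- (h - k + 1L); oj <- (w - k + 1L)
  pos_i <- rep(seq_len(oi), times = oj)
  pos_j <- rep(seq_len(oj), each = oi)
  off <- expand.grid(di = 0:(k - 1L), dj = 0:(k - 1L))
  idx <- matrix(0L, oi * oj, k * k)
  for (c in seq_len(k * k)) {
    idx[, c] <- (pos_j + off$dj[c] - 1L) * h + (pos_i + off$di[c])
  }
  idx
}

cnn_forward <- function(net, xmat) {
  # xmat: pixels x n (already centered per image)
  n <- ncol(xmat)
  npos <- nrow(net$idx); k2 <- ncol(net$idx)
  A <- matrix(0, npos * n, k2)
  for (c in seq_len(k2)) A[, c] <- as.vector(xmat[net$idx[, c], , drop = FALSE])
  Z <- A %*% net$Wc
  act <- if (net$activation == "relu") pmax(Z, 0) else Z^2
  g <- rep(seq_len(n), each = npos)
  pool <- rowsum(act, g) / npos
  feat <- if (net$feature == "log_energy") log(pool + net$eps) else pool
  logits <- feat %*% net$V + matrix(net$b, n, length(net$b), byrow = TRUE)
  ex <- exp(logits - apply(logits, 1L, max))
  probs <- ex / rowSums(ex)
  list(A = A, Z = Z, pool = pool, feat = feat, probs = probs, g = g, n = n)
}

cnn_predict <- function(net, batch) {
  xmat <- vapply(batch, function(im) {
    v <- as.vector(to_grayscale(im))
    v - mean(v)
  }, numeric(net$h * net$w))
  if (is.null(dim(xmat))) xmat <- matrix(xmat, ncol = 1L)
  cnn_forward(net, xmat)$probs
}

cnn_input_gradient <- function(net, image, target) {
  x <- as.vector(to_grayscale(image))
  xmat <- matrix(x - mean(x), ncol = 1L)
  fw <- cnn_forward(net, xmat)
  dlogits <- fw$probs
  dlogits[1L, target] <- dlogits[1L, target] - 1   # d(-log p_t)/dlogits
  dfeat <- dlogits %*% t(net$V)
  dpool <- if (net$feature == "log_energy") dfeat / (fw$pool + net$eps) else dfeat
  dact <- dpool[fw$g, , drop = FALSE] / nrow(net$idx)
  dZ <- if (net$activation == "relu") (fw$Z > 0) * dact else 2 * fw$Z * dact
  dA <- dZ %*% t(net$Wc)
  acc <- rowsum(as.vector(dA), group = as.vector(net$idx))
  dx <- numeric(net$h * net$w)
  dx[as.integer(rownames(acc))] <- acc[, 1L]
  dx <- dx - mean(dx)                              # adjoint of per-image centering
  out <- matrix(dx, net$h, net$w)
  if (length(dim(image)) == 3L) {
    # luminance conversion adjoint
    arr <- array(0, dim = dim(image))
    wts <- c(0.299, 0.587, 0.114)
    for (c in seq_len(dim(image)[3L])) arr[, , c] <- wts[c] * out
    arr
  } else {
    out
  }
}

#' Train a tiny convolutional classifier
#'
#' A small (well under 50k parameters) convolutional network: `n_filters`
#' k x k filters, quadratic activation, spatial mean pooling of the filter
#' energies, log transform, and a softmax readout. The quadratic/energy
#' architecture makes the model a trainable bank of frequency-selective
#' energy detectors -- well matched to band-structured data while remaining
#' fully differentiable for gradient-based attacks. Trained with Adam on the
#' cross-entropy; bit-reproducible given `seed`.
#'
#' @param dataset A `band_dataset` or a list with `images` and `labels`.
#' @param epochs Training epochs.
#' @param seed Seed for initialization and minibatch shuffling.
#' @param preprocess Optional `defense`; training images are passed through
#'   it and the returned handle is the composed model (attacks then chain
#'   gradients through the defense).
#' @param n_filters,ksize Convolution width and kernel size.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param activation Filter nonlinearity: `"relu"` (default, the field's
#'   standard, whose input sensitivity does not vanish on weak signal
#'   components) or `"square"` (energy detector).
#' @param feature Pooled-feature transform fed to the softmax readout:
#'   `"energy"` (raw mean filter energy, the default -- keeps the model's
#'   sensitivity proportional to signal amplitude, as in standard networks)
#'   or `"log_energy"` (scale-invariant log energies).
#' @return A `classifier_handle` with attributes `train_accuracy` and
#'   `converged` (FALSE, with a warning, if training accuracy ends below
#'   0.8).
#' @export
train_tiny_cnn <- function(dataset, epochs = 20L, seed = 0L, preprocess = NULL,
                           n_filters = 8L, ksize = 7L, lr = 0.02,
                           batch_size = 64L,
                           activation = c("relu", "square"),
                           feature = c("energy", "log_energy")) {
  activation <- match.arg(activation)
  feature <- match.arg(feature)
  images <- dataset$images; labels <- as.integer(dataset$labels)
  stopifnot(length(images) == length(labels), length(unique(labels)) >= 2L)
  if (!is.null(preprocess)) {
    stopifnot(inherits(preprocess, "defense"))
    images <- lapply(images, preprocess$forward)
  }
  gray <- lapply(images, to_grayscale)
  h <- nrow(gray[[1L]]); w <- ncol(gray[[1L]])
  K <- max(labels)
  n <- length(gray)
  xall <- vapply(gray, function(im) { v <- as.vector(im); v - mean(v) },
                 numeric(h * w))
  net <- with_seed(seed, list(
    h = h, w = w, k = as.integer(ksize), eps = 1e-6, feature = feature,
    activation = activation,
    idx = im2col_idx(h, w, as.integer(ksize)),
    Wc = matrix(stats::rnorm(ksize^2 * n_filters, 0, 1 / ksize), ksize^2, n_filters),
    V = matrix(stats::rnorm(n_filters * K, 0, 0.1), n_filters, K),
    b = rep(0, K)
  ))
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), labels)] <- 1
  # Adam state
  ms <- list(Wc = 0 * net$Wc, V = 0 * net$V, b = 0 * net$b)
  vs <- ms
  b1 <- 0.9; b2 <- 0.999; ad_eps <- 1e-8; t <- 0L
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        sel <- ord[start:min(start + batch_size - 1L, n)]
        fw <- cnn_forward(net, xall[, sel, drop = FALSE])
        nb <- length(sel)
        dlogits <- (fw$probs - Y[sel, , drop = FALSE]) / nb
        gV <- t(fw$feat) %*% dlogits
        gb <- colSums(dlogits)
        dfeat <- dlogits %*% t(net$V)
        dpool <- if (net$feature == "log_energy") dfeat / (fw$pool + net$eps) else dfeat
        dact <- dpool[fw$g, , drop = FALSE] / nrow(net$idx)
        dZ <- if (net$activation == "relu") (fw$Z > 0) * dact else 2 * fw$Z * dact
        gW <- t(fw$A) %*% dZ
        t <- t + 1L
        for (nm in c("Wc", "V", "b")) {
          gr <- switch(nm, Wc = gW, V = gV, b = gb)
          ms[[nm]] <- b1 * ms[[nm]] + (1 - b1) * gr
          vs[[nm]] <- b2 * vs[[nm]] + (1 - b2) * gr^2
          mh <- ms[[nm]] / (1 - b1^t)
          vh <- vs[[nm]] / (1 - b2^t)
          net[[nm]] <- net[[nm]] - lr * mh / (sqrt(vh) + ad_eps)
        }
      }
    }
  })
  train_acc <- mean(max.col(cnn_forward(net, xall)$probs, ties.method = "first") == labels)
  converged <- train_acc >= 0.8
  if (!converged) {
    warning(sprintf("tiny CNN did not converge: train accuracy %.3f < 0.8", train_acc))
  }
  shape <- if (length(dim(dataset$images[[1L]])) == 3L) {
    dim(dataset$images[[1L]])
  } else {
    c(h, w)
  }
  raw <- classifier_handle(
    n_classes = K, input_shape = shape,
    predict = function(batch) cnn_predict(net, batch),
    loss_gradient = function(image, target) cnn_input_gradient(net, image, target),
    name = sprintf("tiny_cnn(F=%d,k=%d,seed=%d)", n_filters, ksize, seed)
  )
  out <- if (is.null(preprocess)) raw else compose(preprocess, raw)
  attr(out, "train_accuracy") <- train_acc
  attr(out, "converged") <- converged
  out
}
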
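# Representational-similarity eigenanalysis and linear receptive-field
# approximation of principal components.

#' Pairwise cosine-similarity matrix of a response set
#'
#' `S[i, j] = cos(r_i, r_j)` over stimulus rows of a stimuli x neurons
#' response matrix. Invariant to positive per-row rescaling.
#'
#' @param responses Numeric matrix, stimuli in rows, neurons in columns. No
#'   all-zero rows.
#' @return Symmetric matrix with unit diagonal, values in `[-1, 1]`.
#' @export
similarity_matrix <- function(responses) {
  responses <- as.matrix(responses)
  nrm <- sqrt(rowSums(responses^2))
  bad <- which(nrm == 0)
  if (length(bad)) {
    stop(sprintf("stimulus row(s) with all-zero response: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  Rn <- responses / nrm
  S <- tcrossprod(Rn)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  pmin(pmax(S, -1), 1)
}

#' Eigendecomposition of a similarity matrix
#'
#' Spectral decomposition with eigenvalues sorted in descending order and a
#' deterministic sign convention (the largest-magnitude entry of each
#' eigenvector is positive). For a valid cosine-similarity matrix the
#' eigenvalues are real and sum to the number of stimuli.
#'
#' @param similarity Symmetric matrix (asymmetry beyond 1e-8 is an error).
#' @return List with `values` (descending) and `vectors` (columns).
#' @export
eigendecompose_similarity <- function(similarity) {
  similarity <- as.matrix(similarity)
  if (max(abs(similarity - t(similarity))) > 1e-8) {
    stop("similarity matrix is not symmetric")
  }
  e <- eigen((similarity + t(similarity)) / 2, symmetric = TRUE)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  list(values = e$values, vectors = V)
}

#' Linear receptive-field approximation of a principal component
#'
#' Regresses per-stimulus component scores onto pixel intensities with ridge
#' regularization, giving the image-shaped linear map that best predicts the
#' component: an estimate of the receptive field behind that representational
#' dimension. Solved in the dual form, so stimulus counts far below the pixel
#' count are handled without forming an N x N system.
#'
#' @param scores Numeric vector of per-stimulus scores (e.g. an eigenvector
#'   of the similarity matrix).
#' @param stimulus_images List of images, one per score.
#' @param ridge Dimensionless regularization weight; the actual penalty is
#'   `ridge * mean squared stimulus norm`, so the default `1e-3` is a small
#'   fraction of the data scale. Larger values shrink the map toward zero.
#' @return Image-shaped spatial map (class of the first stimulus).
#' @export
linear_rf_approximation <- function(scores, stimulus_images, ridge = 1e-3) {
  stopifnot(length(scores) == length(stimulus_images), length(scores) >= 1L,
            all(is.finite(scores)), ridge >= 0)
  d0 <- dim(stimulus_images[[1L]])
  X <- t(vapply(stimulus_images, function(im) as.vector(im), numeric(prod(d0))))
  Xc <- sweep(X, 2L, colMeans(X))
  yc <- scores - mean(scores)
  G <- tcrossprod(Xc)
  lambda <- ridge * sum(diag(G)) / nrow(G) + 1e-12
  alpha <- solve(G + lambda * diag(nrow(G)), yc)
  beta <- as.vector(crossprod(Xc, alpha))
  out <- stimulus_images[[1L]]
  out[] <- beta
  out
}

#' Spectral band-energy fraction of a spatial map
#'
#' Fraction of the map's total Fourier power (DC excluded) carried by bins
#' with radial frequency at or below `cutoff`. Used to verify that recovered
#' receptive fields are low-frequency.
#'
#' @param map Image-shaped spatial map.
#' @param cutoff Radius in the chosen units.
#' @param mode Frequency normalization (default `"nyquist"`).
#' @return Scalar in `[0, 1]`.
#' @export
band_energy_fraction <- function(map, cutoff, mode = c("nyquist", "sampling")) {
  mode <- match.arg(mode)
  sp <- power_spectrum(map, mode)
  dc <- sp$grid$radius == 0
  tot <- sum(sp$values[!dc])
  if (tot == 0) return(NA_real_)
  sum(sp$values[!dc & sp$grid$radius <= cutoff + 1e-12]) / tot
}

#' Receptive-field maps of the leading similarity components
#'
#' Convenience pipeline: eigendecompose the cosine-similarity matrix of a
#' response set and regress each of the top eigenvectors onto the stimulus
#' pixels. Map signs follow the regression convention (largest-magnitude
#' coefficient positive).
#'
#' @param responses A `neural_response_set` (see [make_synthetic_v1()]) or a
#'   stimuli x neurons matrix plus `stimulus_images`.
#' @param stimulus_images Required when `responses` is a bare matrix.
#' @param top Number of leading components to map.
#' @param ridge Passed to [linear_rf_approximation()].
#' @return List with `eigenvalues`, `maps` (list of images), and
#'   `trace_fraction` captured by the mapped components.
#' @export
rf_maps <- function(responses, stimulus_images = NULL, top = 3L, ridge = 1e-3) {
  if (inherits(responses, "neural_response_set")) {
    stimulus_images <- responses$stimulus_images
    responses <- responses$responses
  }
  stopifnot(!is.null(stimulus_images))
  S <- similarity_matrix(responses)
  e <- eigendecompose_similarity(S)
  top <- min(top, ncol(e$vectors))
  maps <- lapply(seq_len(top), function(j) {
    m <- linear_rf_approximation(e$vectors[, j], stimulus_images, ridge)
    if (m[which.max(abs(m))] < 0) m <- -m
    m
  })
  list(eigenvalues = e$values, maps = maps,
       trace_fraction = sum(e$values[seq_len(top)]) / sum(e$values))
}
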
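# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of their
#' seed argument without disturbing the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Validate an image: numeric matrix (H x W) or array (H x W x C), finite.
check_image <- function(x, arg = "image") {
  if (is.null(dim(x)) || !(length(dim(x)) %in% c(2L, 3L))) {
    stop(sprintf("`%s` must be an H x W matrix or H x W x C array", arg))
  }
  if (any(dim(x) == 0L)) stop(sprintf("`%s` is empty", arg))
  if (!is.numeric(x)) stop(sprintf("`%s` must be numeric", arg))
  if (!all(is.finite(x))) stop(sprintf("`%s` contains non-finite pixels", arg))
  invisible(x)
}

image_dim <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) c(d, 1L) else d
}

# Split into a list of single-channel matrices.
image_channels <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) return(list(x))
  lapply(seq_len(d[3L]), function(k) x[, , k])
}

# Reassemble channels into the shape of `like`.
channels_to_image <- function(chans, like) {
  if (length(dim(like)) == 2L) return(chans[[1L]])
  out <- array(0, dim = dim(like))
  for (k in seq_along(chans)) out[, , k] <- chans[[k]]
  out
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# fftshift index permutation for length n (DC moves to floor(n/2)+1).
shift_idx <- function(n) {
  ce <- ceiling(n / 2)
  c((ce + 1L):n, 1L:ce)
}

# inverse permutation (DC back to index 1)
ishift_idx <- function(n) {
  fl <- floor(n / 2)
  c((fl + 1L):n, 1L:fl)
}

fftshift2 <- function(m) m[shift_idx(nrow(m)), shift_idx(ncol(m))]
ifftshift2 <- function(m) m[ishift_idx(nrow(m)), ishift_idx(ncol(m))]

#' Convert an RGB image to grayscale luminance
#'
#' Uses the fixed Rec. 601 weights (0.299, 0.587, 0.114). Idempotent on
#' grayscale (matrix) inputs.
#'
#' @param image Matrix or H x W x 3 array with values in any real range.
#' @return An H x W matrix.
#' @export
to_grayscale <- function(image) {
  check_image(image)
  if (length(dim(image)) == 2L) return(image)
  if (dim(image)[3L] == 1L) return(image[, , 1L])
  if (dim(image)[3L] != 3L) stop("expected 1 or 3 channels")
  0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
}
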
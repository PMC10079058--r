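# Reading and writing the package's standard artifacts: 8-bit PNG images
# (rescaled to [0, 1]) and CSV exports of profiles, curves, bases and
# response matrices.

#' Read an image from a PNG file
#'
#' 8-bit (or 16-bit) PNG, returned with values in `[0, 1]`. Alpha channels
#' are dropped; grayscale files come back as matrices, color files as
#' H x W x 3 arrays.
#'
#' @param path PNG file path.
#' @return Image matrix or array in `[0, 1]`.
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L && dim(x)[3L] %in% c(2L, 4L)) {
    x <- x[, , seq_len(dim(x)[3L] - 1L), drop = FALSE]
  }
  if (length(dim(x)) == 3L && dim(x)[3L] == 1L) x <- x[, , 1L]
  x
}

#' Write an image to a PNG file
#'
#' Values are clipped to `[0, 1]` before quantization (hybrid images, which
#' are deliberately unclipped in memory, are only clipped at export).
#'
#' @param image Image matrix or array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  check_image(image)
  png::writePNG(clip01(image), path)
  invisible(path)
}

#' Read a labeled image directory
#'
#' Expects one subdirectory per class, each containing PNG images; class ids
#' are assigned in sorted subdirectory order.
#'
#' @param dir Root directory.
#' @return List with `images`, `labels`, and `class_names`.
#' @export
read_image_dir <- function(dir) {
  classes <- sort(list.dirs(dir, recursive = FALSE))
  if (length(classes) == 0L) stop(sprintf("no class subdirectories in '%s'", dir))
  images <- list(); labels <- integer(0)
  for (k in seq_along(classes)) {
    files <- sort(list.files(classes[k], pattern = "\\.png$", full.names = TRUE))
    for (f in files) {
      images[[length(images) + 1L]] <- read_image_png(f)
      labels <- c(labels, k)
    }
  }
  list(images = images, labels = labels, class_names = basename(classes))
}

#' Convert package result objects to data frames
#'
#' @param x A `radial_profile`, `probe_curve`, or list of `attack_result`s.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.radial_profile <- function(x, ...) {
  data.frame(radius = x$radii, cum_fraction = x$cum_fraction)
}

#' @rdname as.data.frame.radial_profile
#' @export
as.data.frame.probe_curve <- function(x, ...) {
  data.frame(f_mix = x$f_mix, p_low = x$p_low, p_high = x$p_high,
             n = x$n_images)
}

#' Write a radial profile or probe curve to CSV
#'
#' @param x A `radial_profile` or `probe_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Persist a PCA basis as CSV files
#'
#' Writes `<stem>_mean.csv`, `<stem>_components.csv` (N x K) and
#' `<stem>_eigenvalues.csv`.
#'
#' @param basis A `pca_basis`.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_pca_basis <- function(basis, stem) {
  stopifnot(inherits(basis, "pca_basis"))
  utils::write.csv(data.frame(mean = basis$mean),
                   paste0(stem, "_mean.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(basis$components),
                   paste0(stem, "_components.csv"), row.names = FALSE)
  utils::write.csv(data.frame(eigenvalue = basis$eigenvalues),
                   paste0(stem, "_eigenvalues.csv"), row.names = FALSE)
  invisible(stem)
}

#' Read a stimuli x neurons response matrix from CSV
#'
#' @param path CSV with one row per stimulus, one column per neuron.
#' @return Numeric matrix.
#' @export
read_responses_csv <- function(path) {
  as.matrix(utils::read.csv(path))
}
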
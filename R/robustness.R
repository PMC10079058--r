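# Minimal-L-infinity-perturbation search (PGD + outer bisection, candidates
# aggregated over engines and seeds), success-rate curves, and the
# corruption-accuracy harness.

#' Classifier handle: the probe/attack contract
#'
#' Every model probed or attacked by this package satisfies this contract:
#' batched class probabilities and, optionally, the per-pixel gradient of the
#' targeted cross-entropy loss `-log p_target(x)` with respect to the input.
#'
#' @param n_classes Number of classes.
#' @param input_shape Integer vector `c(H, W)` or `c(H, W, C)`.
#' @param predict Function: list of images -> n x n_classes matrix of
#'   probabilities (rows sum to 1).
#' @param loss_gradient Optional function `(image, target)` -> gradient array
#'   of the same shape as the image. `NULL` for probe-only models.
#' @param name Provenance string.
#' @return A `classifier_handle`.
#' @export
classifier_handle <- function(n_classes, input_shape, predict,
                              loss_gradient = NULL, name = "model") {
  stopifnot(is.function(predict), n_classes >= 2)
  structure(list(n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape),
                 predict = predict, loss_gradient = loss_gradient,
                 name = name),
            class = "classifier_handle")
}

#' @export
print.classifier_handle <- function(x, ...) {
  cat(sprintf("<classifier_handle> %s: %s input, %d classes, gradient: %s\n",
              x$name, paste(x$input_shape, collapse = "x"), x$n_classes,
              if (is.null(x$loss_gradient)) "no" else "yes"))
  invisible(x)
}

top1 <- function(model, images) {
  max.col(model$predict(images), ties.method = "first")
}

#' Targeted PGD attack at a fixed budget
#'
#' Projected gradient descent on the targeted loss `-log p_target`: iterative
#' signed-gradient steps of size `2.5 * epsilon / steps`, each followed by
#' projection onto the L-infinity ball of radius `epsilon` intersected with
#' `[0, 1]`. Starts from a random point inside the ball (controlled by
#' `seed`). Succeeds as soon as an iterate's top-1 prediction equals the
#' target.
#'
#' @param model `classifier_handle` with a gradient.
#' @param image Clean image with values in `[0, 1]`.
#' @param target Target class id.
#' @param epsilon L-infinity budget, `0 < epsilon <= 0.5`.
#' @param steps Number of PGD iterations.
#' @param seed Seed for the random start.
#' @return List with `success` flag and `candidate` image (always inside the
#'   ball and inside `[0, 1]`).
#' @export
pgd_targeted <- function(model, image, target, epsilon, steps = 100L, seed = 0L) {
  if (is.null(model$loss_gradient)) {
    stop(sprintf("model '%s' provides no input gradient", model$name))
  }
  stopifnot(epsilon > 0, epsilon <= 0.5)
  check_image(image)
  lo <- pmax(image - epsilon, 0)
  hi <- pmin(image + epsilon, 1)
  x <- with_seed(seed, {
    delta <- array(stats::runif(length(image), -epsilon, epsilon), dim = dim(image))
    pmin(pmax(image + delta, lo), hi)
  })
  alpha <- 2.5 * epsilon / steps
  best <- NULL
  for (s in seq_len(steps)) {
    if (top1(model, list(x))[1L] == target) { best <- x; break }
    g <- model$loss_gradient(x, target)
    x <- pmin(pmax(x - alpha * sign(g), lo), hi)
  }
  if (is.null(best) && top1(model, list(x))[1L] == target) best <- x
  list(success = !is.null(best), candidate = if (is.null(best)) x else best)
}

#' Built-in PGD attack engine
#'
#' Wraps [pgd_targeted()] as an engine of signature
#' `function(model, image, target, epsilon, seed)`, the plug-in interface of
#' [minimal_perturbation()]. External attack implementations with the same
#' signature can be supplied alongside it.
#'
#' @param steps PGD iterations per call (default 100).
#' @return An engine function (class `attack_engine`).
#' @export
pgd_engine <- function(steps = 100L) {
  f <- function(model, image, target, epsilon, seed) {
    pgd_targeted(model, image, target, epsilon, steps = steps, seed = seed)
  }
  structure(f, class = c("attack_engine", "function"), name = sprintf("pgd%d", steps))
}

#' Minimal targeted L-infinity perturbation
#'
#' Finds the smallest L-infinity perturbation flipping the prediction to
#' `target` by running an outer bisection on the budget epsilon (bracket
#' `[0, 0.5]`, tolerance 0.5/255) around each attack engine and random seed,
#' then keeping the candidate with the smallest measured perturbation over
#' all engines x seeds -- the aggregation protocol for strong attacks.
#'
#' @param model `classifier_handle` with a gradient.
#' @param image Clean image in `[0, 1]`.
#' @param target Target class id. If the image is already classified as
#'   `target`, the result has `epsilon_min = 0`.
#' @param engines List of engine functions (default: the PGD engine).
#' @param n_seeds Random restarts per engine.
#' @param seed Base seed; restart r of engine e uses `seed + r - 1`.
#' @param tol Bisection tolerance on epsilon (default 0.5/255).
#' @param eps_max Bracket upper end (default 0.5).
#' @param image_id Optional identifier carried into the result.
#' @return An `attack_result`: `image_id`, `target_class`, `epsilon_min`
#'   (in `[0,1]` units; multiply by 255 for the display convention),
#'   `adversarial`, `engine` provenance, `converged` flag.
#' @export
minimal_perturbation <- function(model, image, target,
                                 engines = list(pgd_engine()),
                                 n_seeds = 1L, seed = 0L,
                                 tol = 0.5 / 255, eps_max = 0.5,
                                 image_id = NA_integer_) {
  check_image(image)
  if (top1(model, list(image))[1L] == target) {
    return(structure(list(image_id = image_id, target_class = target,
                          epsilon_min = 0, adversarial = image,
                          engine = "none", converged = TRUE),
                     class = "attack_result"))
  }
  best_eps <- Inf; best_adv <- NULL; best_engine <- NA_character_
  fallback_adv <- image
  for (e in seq_along(engines)) {
    eng <- engines[[e]]
    ename <- attr(eng, "name")
    if (is.null(ename)) ename <- sprintf("engine%d", e)
    for (r in seq_len(n_seeds)) {
      s <- seed + r - 1L
      at <- eng(model, image, target, eps_max, s)
      if (!at$success) { fallback_adv <- at$candidate; next }
      lo <- 0; hi <- eps_max; adv <- at$candidate
      while (hi - lo > tol) {
        mid <- (hi + lo) / 2
        am <- eng(model, image, target, mid, s)
        if (am$success) { hi <- mid; adv <- am$candidate } else lo <- mid
      }
      eps <- max(abs(adv - image))
      if (eps < best_eps) {
        best_eps <- eps; best_adv <- adv
        best_engine <- sprintf("%s/seed%d", ename, s)
      }
    }
  }
  if (is.null(best_adv)) {
    return(structure(list(image_id = image_id, target_class = target,
                          epsilon_min = NA_real_, adversarial = fallback_adv,
                          engine = "none", converged = FALSE),
                     class = "attack_result"))
  }
  structure(list(image_id = image_id, target_class = target,
                 epsilon_min = best_eps, adversarial = best_adv,
                 engine = best_engine, converged = TRUE),
            class = "attack_result")
}

#' Draw fixed attack targets
#'
#' One target class per image, drawn uniformly from the classes different
#' from the true label, deterministic given `seed` -- the targets stay fixed
#' across models so attack comparisons are paired.
#'
#' @param labels True class labels.
#' @param n_classes Total number of classes.
#' @param seed Integer seed.
#' @return Integer vector of target classes.
#' @export
draw_attack_targets <- function(labels, n_classes, seed = 0L) {
  with_seed(seed, vapply(labels, function(y) {
    cand <- setdiff(seq_len(n_classes), y)
    cand[sample.int(length(cand), 1L)]
  }, integer(1)))
}

#' Attack success-rate curve and epsilon at 50%
#'
#' `s(eps)` is the fraction of attack results with `epsilon_min <= eps`;
#' non-converged (censored) results count as failures at every budget rather
#' than being dropped, which would bias the curve upward. `eps50` is the
#' first upward crossing of 0.5, linearly interpolated on the grid.
#'
#' @param results List of `attack_result`s.
#' @param epsilon_grid Budgets at which to evaluate the curve; default is a
#'   dense grid over the observed range.
#' @return List with `epsilon`, `success_rate`, and `eps50` (NA if the curve
#'   never reaches 0.5).
#' @export
success_curve <- function(results, epsilon_grid = NULL) {
  stopifnot(length(results) > 0L)
  eps <- vapply(results, function(r) {
    if (isTRUE(r$converged)) r$epsilon_min else Inf
  }, numeric(1))
  if (is.null(epsilon_grid)) {
    top <- max(eps[is.finite(eps)], 1 / 255)
    epsilon_grid <- seq(0, top, length.out = 512L)
  }
  s <- vapply(epsilon_grid, function(e) mean(eps <= e), numeric(1))
  eps50 <- if (any(s >= 0.5)) half_crossing(epsilon_grid, s, 0.5) else NA_real_
  list(epsilon = epsilon_grid, success_rate = s, eps50 = eps50)
}

#' Accuracy under a corruption suite
#'
#' Applies every corruption spec in the suite to the clean set and records
#' classification accuracy per (corruption, severity) cell, plus per-severity
#' averages over corruptions and per-frequency-group averages over member
#' cells (members x severities).
#'
#' @param model A `classifier_handle`.
#' @param images List of clean images in `[0, 1]`.
#' @param labels True class labels.
#' @param suite List of `corruption_spec`s, e.g. from [corruption_suite()].
#' @return A `corruption_report`: `cells` data frame (name, severity, group,
#'   accuracy, n), `by_severity`, `by_group`, `clean_accuracy`, and
#'   `per_image` (logical images x cells correctness matrix, for paired
#'   model comparisons).
#' @export
corruption_accuracy <- function(model, images, labels, suite) {
  stopifnot(length(images) == length(labels), length(suite) > 0L)
  labels <- as.integer(labels)
  per_image <- matrix(NA, length(images), length(suite))
  rows <- lapply(seq_along(suite), function(si) {
    spec <- suite[[si]]
    corrupted <- lapply(seq_along(images), function(i) {
      sp <- spec
      sp$seed <- spec$seed + i - 1L   # independent draws per image
      apply_corruption(images[[i]], sp)
    })
    ok <- top1(model, corrupted) == labels
    per_image[, si] <<- ok
    data.frame(name = spec$name, severity = spec$severity,
               group = spec$group, accuracy = mean(ok), n = length(images))
  })
  cells <- do.call(rbind, rows)
  by_severity <- stats::aggregate(accuracy ~ severity, cells, mean)
  by_group <- stats::aggregate(accuracy ~ group, cells, mean)
  clean <- mean(top1(model, images) == labels)
  structure(list(cells = cells, by_severity = by_severity,
                 by_group = by_group, clean_accuracy = clean,
                 per_image = per_image),
            class = "corruption_report")
}

#' @export
print.corruption_report <- function(x, ...) {
  cat(sprintf("<corruption_report> %d cells, clean accuracy %.3f\n",
              nrow(x$cells), x$clean_accuracy))
  print(x$by_group)
  invisible(x)
}

#' Export attack results as JSON lines
#'
#' One JSON object per result (image id, target, epsilon in both `[0,1]` and
#' `/255` units, engine, convergence); the adversarial image itself is not
#' serialized.
#'
#' @param results List of `attack_result`s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_attack_results <- function(results, path) {
  lines <- vapply(results, function(r) {
    jsonlite::toJSON(list(image_id = r$image_id, target_class = r$target_class,
                          epsilon_min = r$epsilon_min,
                          epsilon_min_x255 = r$epsilon_min * 255,
                          engine = r$engine, converged = r$converged),
                     auto_unbox = TRUE, digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
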
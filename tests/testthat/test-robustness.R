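# helper: 2-class linear model with a prescribed closed-form attack margin
planted_linear <- function(seed, target_eps) {
  set.seed(seed)
  W <- matrix(stats::rnorm(2 * 16), 2, 16)
  x <- matrix(stats::runif(16, 0.35, 0.65), 4, 4)
  s <- W %*% as.vector(x)
  cur <- which.max(s); tgt <- 3 - cur
  b <- c(0, 0)
  b[tgt] <- as.numeric(s[cur] - s[tgt]) -
    target_eps * sum(abs(W[tgt, ] - W[cur, ]))
  list(model = make_linear_classifier(W, b, c(4, 4)), x = x,
       cur = cur, tgt = tgt,
       closed = brute_linear_margin(W, b, as.vector(x), cur, tgt))
}

test_that("classifier handles validate probabilities and report gradients", {
  m <- constant_model(2, 3, c(4, 4))
  p <- m$predict(list(rand_image(4, 4, 1)))
  expect_equal(rowSums(p), 1, tolerance = 1e-6)
  expect_error(pgd_targeted(m, rand_image(4, 4, 1), 1, 0.1),
               "no input gradient")
})

test_that("pgd candidates respect the ball and the box", {
  pl <- planted_linear(1, 0.2)
  res <- pgd_targeted(pl$model, pl$x, pl$tgt, epsilon = 0.1, steps = 20,
                      seed = 3)
  expect_true(all(res$candidate >= 0 & res$candidate <= 1))
  expect_lte(max(abs(res$candidate - pl$x)), 0.1 + 1e-12)
})

test_that("pgd succeeds at a generous budget on separable linear models", {
  ok <- 0
  for (seed in 1:20) {
    pl <- planted_linear(seed, runif(1, 0.1, 0.3))
    res <- pgd_targeted(pl$model, pl$x, pl$tgt, epsilon = 0.5, steps = 50,
                        seed = seed)
    ok <- ok + res$success
  }
  expect_gte(ok / 20, 0.99)
})

test_that("minimal perturbation matches the closed-form linear margin", {
  errs <- vapply(1:10, function(seed) {
    pl <- planted_linear(seed, stats::runif(1, 0.12, 0.35))
    r <- minimal_perturbation(pl$model, pl$x, pl$tgt, n_seeds = 2, seed = 1)
    expect_true(r$converged)
    abs(r$epsilon_min - pl$closed) / pl$closed
  }, numeric(1))
  expect_lt(max(errs), 0.02)
})

test_that("minimal perturbation handles the trivial and censored cases", {
  pl <- planted_linear(2, 0.2)
  # image already classified as the target
  r0 <- minimal_perturbation(pl$model, pl$x, pl$cur)
  expect_equal(r0$epsilon_min, 0)
  expect_true(r0$converged)
  # an engine that never succeeds yields a censored result
  dud <- structure(function(model, image, target, epsilon, seed) {
    list(success = FALSE, candidate = image)
  }, name = "dud")
  rc <- minimal_perturbation(pl$model, pl$x, pl$tgt, engines = list(dud))
  expect_false(rc$converged)
  expect_true(is.na(rc$epsilon_min))
})

test_that("enlarging the engine and seed set never hurts the minimum", {
  pl <- planted_linear(4, 0.25)
  small <- minimal_perturbation(pl$model, pl$x, pl$tgt, n_seeds = 1, seed = 1)
  big <- minimal_perturbation(pl$model, pl$x, pl$tgt,
                              engines = list(pgd_engine(100), pgd_engine(40)),
                              n_seeds = 3, seed = 1)
  expect_lte(big$epsilon_min, small$epsilon_min + 1e-12)
})

test_that("bisection is sound: success at eps_min, failure just below", {
  pl <- planted_linear(6, 0.25)
  r <- minimal_perturbation(pl$model, pl$x, pl$tgt, n_seeds = 1, seed = 2)
  eng <- pgd_engine(100)
  seed_used <- as.integer(sub(".*seed", "", r$engine))
  expect_equal(max.col(pl$model$predict(list(r$adversarial)))[1], pl$tgt)
  below <- eng(pl$model, pl$x, pl$tgt, r$epsilon_min - 2 * 0.5 / 255, seed_used)
  expect_false(below$success)
})

test_that("success curve counts, interpolates, and censors correctly", {
  mk <- function(eps, conv = TRUE) {
    structure(list(epsilon_min = eps, converged = conv), class = "attack_result")
  }
  res <- lapply(c(1, 2, 3) / 255, mk)
  sc <- success_curve(res, epsilon_grid = c(0, 1, 2, 3) / 255)
  expect_equal(sc$success_rate[3], 2 / 3)
  # censored results count as failures at every budget
  res2 <- c(res, list(mk(NA, conv = FALSE)))
  sc2 <- success_curve(res2, epsilon_grid = c(0, 1, 2, 3) / 255)
  expect_equal(sc2$success_rate[4], 3 / 4)
  # symmetric distribution: eps50 approaches the median on a dense grid
  set.seed(10)
  eps <- 0.1 + stats::rbeta(2001, 4, 4) * 0.2   # symmetric around 0.2
  sc3 <- success_curve(lapply(eps, mk),
                       epsilon_grid = seq(0, 0.4, length.out = 4001))
  expect_equal(sc3$eps50, stats::median(eps), tolerance = 0.002)
})

test_that("attack targets are fixed, valid, and deterministic", {
  labs <- rep(1:4, 25)
  t1 <- draw_attack_targets(labs, 4, seed = 3)
  t2 <- draw_attack_targets(labs, 4, seed = 3)
  expect_identical(t1, t2)
  expect_true(all(t1 != labs))
  expect_true(all(t1 %in% 1:4))
})

test_that("corruption accuracy bookkeeping matches brute recounts", {
  imgs <- lapply(1:30, function(i) rand_image(8, 8, i, 0.2, 0.8))
  labs <- rep(1:3, each = 10)
  cheat <- classifier_handle(3, c(8, 8), predict = local({
    labs0 <- labs
    k <- 0L
    function(batch) {
      # label-reading cheat: the harness presents images in dataset order
      n <- length(batch)
      p <- matrix(0, n, 3)
      p[cbind(seq_len(n), labs0[seq_len(n)])] <- 1
      (p + 1e-9) / rowSums(p + 1e-9)
    }
  }), name = "cheat")
  suite <- corruption_suite(c("gaussian_noise", "brightness", "pixelate"),
                            1:2, seed = 5)
  rep_cheat <- corruption_accuracy(cheat, imgs, labs, suite)
  expect_true(all(rep_cheat$cells$accuracy == 1))
  # uniform-random predictor sits at chance within binomial tolerance
  unif <- classifier_handle(3, c(8, 8), predict = function(batch) {
    set.seed(length(batch) + 1L)
    p <- matrix(stats::runif(length(batch) * 3), length(batch), 3)
    p / rowSums(p)
  }, name = "unif")
  rep_unif <- corruption_accuracy(unif, imgs, labs, suite)
  expect_true(all(abs(rep_unif$cells$accuracy - 1 / 3) <= 0.3))
  # group means equal the arithmetic mean of member cells
  for (g in unique(rep_cheat$cells$group)) {
    expect_equal(rep_cheat$by_group$accuracy[rep_cheat$by_group$group == g],
                 mean(rep_cheat$cells$accuracy[rep_cheat$cells$group == g]))
  }
  for (s in unique(rep_cheat$cells$severity)) {
    expect_equal(
      rep_cheat$by_severity$accuracy[rep_cheat$by_severity$severity == s],
      mean(rep_cheat$cells$accuracy[rep_cheat$cells$severity == s]))
  }
})

test_that("attack results serialize as JSON lines", {
  res <- list(structure(list(image_id = 1L, target_class = 2L,
                             epsilon_min = 2 / 255, adversarial = NULL,
                             engine = "pgd100/seed0", converged = TRUE),
                        class = "attack_result"))
  path <- tempfile(fileext = ".jsonl")
  write_attack_results(res, path)
  parsed <- jsonlite::fromJSON(readLines(path)[1])
  expect_equal(parsed$epsilon_min_x255, 2, tolerance = 1e-12)
  expect_true(parsed$converged)
})
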
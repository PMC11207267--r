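test_that("pearson profile matches the direct covariance formula", {
  set.seed(19)
  y <- rep(c(0, 1), 25)
  X <- matrix(rnorm(50 * 78), 50, 78, dimnames = list(NULL, feature_names()))
  X[, 3] <- y                                   # identical to the class
  X[, 7] <- 1 - y                               # anti-identical
  r <- pearson_profile(X, y)
  expect_equal(unname(r[3]), 1)
  expect_equal(unname(r[7]), -1)
  # direct-sum oracle
  oracle <- apply(X, 2, function(v) {
    sum((v - mean(v)) * (y - mean(y))) /
      sqrt(sum((v - mean(v))^2) * sum((y - mean(y))^2))
  })
  expect_equal(unname(r), unname(oracle), tolerance = 1e-12)

  expect_error(pearson_profile(X, rep(1, 50)), "both classes")
  X[, 5] <- 2
  expect_warning(r2 <- pearson_profile(X, y), "constant")
  expect_equal(unname(r2[5]), 0)
})

test_that("top-n mask equals brute-force argsort with index tie-breaks", {
  r <- c(0.9, -0.95, 0.1, rep(0, 75))
  expect_equal(which(top_n_mask(r, 1) == 1), 2L)
  expect_equal(sum(top_n_mask(r, 78)), 78)
  set.seed(23)
  r2 <- round(rnorm(78), 2)                    # rounding forces ties
  for (n in c(5, 10, 40)) {
    m <- top_n_mask(r2, n)
    expect_equal(sum(m), n)
    oracle <- order(-abs(r2), seq_along(r2))[seq_len(n)]
    expect_setequal(which(m == 1), oracle)
  }
  expect_error(top_n_mask(r2, 0), "n must")
  expect_error(top_n_mask(r2, 79), "n must")
})

test_that("evaluate_mask scores separable data perfectly and is deterministic", {
  pf <- make_planted(200, 10, effect = 6)
  mask <- as.integer(seq_len(78) %in% pf$informative)
  s1 <- evaluate_mask(mask, classifier_spec("RF"), pf$X, pf$y, seed = 3)
  expect_equal(unname(s1), c(100, 100))
  expect_identical(s1, evaluate_mask(mask, classifier_spec("RF"), pf$X,
                                     pf$y, seed = 3))
  expect_error(evaluate_mask(rep(0L, 78), classifier_spec("RF"), pf$X, pf$y),
               "empty")
})

test_that("permuted labels score near the majority-class rate", {
  pf <- make_planted(200, 5, effect = 3)
  set.seed(29)
  y_perm <- sample(pf$y)
  s <- evaluate_mask(rep(1L, 78), classifier_spec("RF"), pf$X, y_perm,
                     seed = 29)
  maj <- 100 * max(mean(y_perm), 1 - mean(y_perm))
  expect_lt(abs(s["accuracy"] - maj), 10)
})

test_that("threshold_scan agrees with evaluate_mask and hits recall 100 at 0", {
  pf <- make_planted(120, 5, effect = 2)
  mask <- rep(1L, 78)
  sc <- threshold_scan(mask, classifier_spec("RF"), pf$X, pf$y,
                       c(0, 0.5), repeats = 3, seed = 7)
  em <- evaluate_mask(mask, classifier_spec("RF"), pf$X, pf$y, 0.5,
                      repeats = 3, seed = 7)
  expect_equal(sc$accuracy[sc$threshold == 0.5], unname(em["accuracy"]))
  expect_equal(sc$recall[sc$threshold == 0.5], unname(em["recall"]))
  expect_equal(sc$recall[sc$threshold == 0], 100)  # everything predicted 1
})

test_that("ccf_scan fills the grid and picks the goal-satisfying argmax", {
  pf <- make_planted(150, 8, effect = 4)
  res <- ccf_scan(pf$X, pf$y, classifier_spec("RF"), n_grid = c(8, 78),
                  threshold_grid = c(0.4, 0.5), repeats = 2, seed = 5)
  expect_equal(nrow(res$table), 4)
  expect_true(all(c("n", "threshold", "accuracy", "recall", "fitness")
                  %in% names(res$table)))
  b <- res$best
  expect_true(b$accuracy >= 95 && b$recall >= 97)
  # the best row maximises accuracy among goal-satisfying rows
  ok <- res$table$accuracy >= 95 & res$table$recall >= 97
  expect_equal(b$accuracy, max(res$table$accuracy[ok]))
})

test_that("penalised fitness has the documented closed form", {
  th <- fitness_thresholds(95, 97)
  expect_equal(ga_fitness(0.95, 0.97, th), 0)            # exactly at goal
  expect_equal(ga_fitness(0.96, 0.98, th), 2)            # linear branch
  expect_equal(ga_fitness(0.94, 0.97, th), -1.3)         # -1.3 * 1^1.5
  expect_equal(ga_fitness(0.91, 0.97, th), -1.3 * 4^1.5) # -10.4
  expect_equal(ga_fitness(0.91, 0.97, th), -10.4)
  expect_error(fitness_thresholds(101, 50), "\\[0, 100\\]")
})

test_that("fitness is strictly increasing and the penalty dominates past x = 1", {
  th <- fitness_thresholds(95, 97)
  accs <- seq(0.5, 1, by = 0.025)
  f_acc <- vapply(accs, ga_fitness, numeric(1), recall = 0.97,
                  thresholds = th)
  expect_true(all(diff(f_acc) > 0))
  f_rec <- vapply(accs, function(r) ga_fitness(0.95, r, th), numeric(1))
  expect_true(all(diff(f_rec) > 0))
  for (x in c(1, 2, 4)) {
    expect_lt(ga_fitness((95 - x) / 100, 0.97, th), -x)
  }
})

test_that("single-point crossover recombines and fixes identical parents", {
  p1 <- rep(1L, 78); p2 <- rep(0L, 78)
  kids <- flightclass:::single_point_cross(p1, p2, 30)
  expect_equal(kids[[1]], c(rep(1L, 30), rep(0L, 48)))
  expect_equal(kids[[2]], c(rep(0L, 30), rep(1L, 48)))
  same <- flightclass:::single_point_cross(p1, p1, 10)
  expect_equal(same[[1]], p1)
  expect_equal(same[[2]], p1)
})

test_that("the GA recovers planted informative genes with a stub fitness", {
  pf <- make_planted(500, 5, effect = 3, seed = 101)
  stub <- function(mask) sum(mask[pf$informative])
  run <- ga_select(pf$X, pf$y, fitness_fn = stub,
                   config = ga_config(population = 40, parents = 20,
                                      generations = 15, seed = 12))
  expect_gte(sum(run$best_mask[pf$informative]), 4)
  expect_true(all(diff(run$history$best_so_far) >= 0))
  # bit-reproducible under the same seed
  run2 <- ga_select(pf$X, pf$y, fitness_fn = stub,
                    config = ga_config(population = 40, parents = 20,
                                       generations = 15, seed = 12))
  expect_identical(run$best_mask, run2$best_mask)
  expect_identical(run$history, run2$history)
})

test_that("the wrapper GA improves classifier fitness on planted data", {
  pf <- make_planted(150, 5, effect = 2, seed = 55)
  run <- ga_select(pf$X, pf$y, classifier_spec("DT"), threshold = 0.5,
                   config = ga_config(population = 12, parents = 6,
                                      generations = 6,
                                      thresholds = fitness_thresholds(80, 80),
                                      seed = 8))
  expect_true(all(diff(run$history$best_so_far) >= 0))
  expect_gte(run$best_fitness, run$history$best[1])
  expect_gte(sum(run$best_mask), 1)
  expect_lte(run$evaluations, 12 * 6)
})

test_that("masks survive a JSON round-trip", {
  mask <- top_n_mask(c(rep(0.5, 10), rep(0.1, 68)), 10)
  path <- tempfile(fileext = ".json")
  save_mask(mask, path)
  expect_identical(load_mask(path), mask)
})
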
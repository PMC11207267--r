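#' Pearson correlation profile of features against a binary class
#'
#' One coefficient per feature column, against the class coded 0/1. Features
#' with correlation near zero are considered least discriminative by the
#' correlation filter. Constant columns get `r = 0` with a warning.
#'
#' @param X Feature matrix (>= 2 rows).
#' @param y Binary labels (0/1), both classes present.
#' @return Numeric vector of correlations in `[-1, 1]`, named like the
#'   columns of `X`.
#' @export
pearson_profile <- function(X, y) {
  y <- as.numeric(y)
  stopifnot(is.matrix(X) || is.data.frame(X), nrow(X) >= 2L,
            nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  X <- as.matrix(X)
  sds <- apply(X, 2L, stats::sd)
  r <- suppressWarnings(as.numeric(stats::cor(X, y)))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature column(s): r set to 0",
            call. = FALSE)
    r[sds == 0] <- 0
  }
  names(r) <- colnames(X)
  r
}

#' Mask of the n most class-correlated features
#'
#' Selects the `n` features with the largest `|r|`; ties are broken towards
#' the lower feature index for reproducibility.
#'
#' @param profile Correlation vector from [pearson_profile()].
#' @param n Number of features to keep, `1 <= n <= length(profile)`.
#' @return Integer 0/1 mask of the profile's length.
#' @export
top_n_mask <- function(profile, n) {
  p <- length(profile)
  if (!is.numeric(n) || n < 1L || n > p) stop("n must lie in [1, ", p, "]")
  ord <- order(-abs(profile), seq_len(p))
  mask <- integer(p)
  mask[ord[seq_len(n)]] <- 1L
  mask
}

# stratified train-index draw using the current RNG stream; guarantees both
# classes in train and test whenever each class has >= 2 members
stratified_train_idx <- function(y, test_fraction) {
  idx <- unlist(lapply(split(seq_along(y), y), function(i) {
    n <- length(i)
    ntr <- min(n - 1L, max(1L, round((1 - test_fraction) * n)))
    sample(i, ntr)
  }), use.names = FALSE)
  sort(idx)
}

#' Evaluate a feature mask by repeated stratified hold-out
#'
#' For each repeat: a stratified random split (default 75% train / 25%
#' test), a fresh classifier fit on the masked features, thresholded
#' prediction on the test set, accuracy and recall. Returns the means across
#' repeats in percent — the score a feature-selection method is judged by.
#'
#' @param mask Integer 0/1 mask over the columns of `X` (>= 1 selected).
#' @param spec A [classifier_spec].
#' @param X Feature matrix (normalised).
#' @param y Binary labels 0/1.
#' @param threshold Decision threshold.
#' @param repeats Number of independent splits (default 5).
#' @param test_fraction Held-out fraction (default 0.25).
#' @param seed Integer seed; fixed seed gives identical results on rerun.
#' @return Named numeric vector `c(accuracy =, recall =)` in percent.
#' @export
evaluate_mask <- function(mask, spec, X, y, threshold = 0.5, repeats = 5L,
                          test_fraction = 0.25, seed = 1L) {
  if (sum(mask) < 1L) stop("empty feature mask")
  stopifnot(length(mask) == ncol(X))
  Xm <- X[, mask == 1L, drop = FALSE]
  set.seed(seed)
  acc <- rec <- numeric(repeats)
  for (i in seq_len(repeats)) {
    tr <- stratified_train_idx(y, test_fraction)
    fit_seed <- sample.int(.Machine$integer.max, 1L)
    model <- train_classifier(spec, Xm[tr, , drop = FALSE], y[tr], fit_seed)
    pred <- predict_with_threshold(model, Xm[-tr, , drop = FALSE], threshold)
    m <- cm_metrics(confusion(y[-tr], pred))
    acc[i] <- m$accuracy; rec[i] <- m$recall
  }
  c(accuracy = 100 * mean(acc), recall = 100 * mean(rec))
}

#' Score one mask across a threshold grid
#'
#' Fits one model per repeat and reuses its test-set probabilities for every
#' threshold, so the scan costs `repeats` fits regardless of grid size.
#'
#' @inheritParams evaluate_mask
#' @param thresholds Numeric vector of thresholds in `[0, 1]`.
#' @return `data.frame` with `threshold`, `accuracy`, `recall` (percent).
#' @export
threshold_scan <- function(mask, spec, X, y, thresholds, repeats = 5L,
                           test_fraction = 0.25, seed = 1L) {
  if (sum(mask) < 1L) stop("empty feature mask")
  stopifnot(all(thresholds >= 0 & thresholds <= 1))
  Xm <- X[, mask == 1L, drop = FALSE]
  set.seed(seed)
  acc <- rec <- matrix(0, repeats, length(thresholds))
  for (i in seq_len(repeats)) {
    tr <- stratified_train_idx(y, test_fraction)
    fit_seed <- sample.int(.Machine$integer.max, 1L)
    model <- train_classifier(spec, Xm[tr, , drop = FALSE], y[tr], fit_seed)
    prob <- predict_prob(model, Xm[-tr, , drop = FALSE])
    yte <- y[-tr]
    for (k in seq_along(thresholds)) {
      m <- cm_metrics(confusion(yte, as.integer(prob >= thresholds[k])))
      acc[i, k] <- m$accuracy; rec[i, k] <- m$recall
    }
  }
  data.frame(threshold = thresholds, accuracy = 100 * colMeans(acc),
             recall = 100 * colMeans(rec))
}

#' Goal thresholds for the penalised fitness
#'
#' Accuracy/recall goals in percent below which the GA fitness turns sharply
#' negative. The application's stated goals are (95, 97) for aeroplane/bird
#' and (75, 90) for big-raptor/other-bird.
#'
#' @param th_a,th_r Accuracy and recall goals in percent, in `[0, 100]`.
#' @return List with `th_a`, `th_r`.
#' @export
fitness_thresholds <- function(th_a = 95, th_r = 97) {
  if (th_a < 0 || th_a > 100 || th_r < 0 || th_r > 100)
    stop("fitness thresholds must lie in [0, 100]")
  list(th_a = th_a, th_r = th_r)
}

#' Threshold-penalised GA fitness
#'
#' With `A = 100 * accuracy - th_a` and `R = 100 * recall - th_r`, each
#' component equals its modified score when non-negative and
#' `-1.3 * |score|^(3/2)` when negative; the fitness is their sum. The
#' superlinear penalty drives the search away from masks that miss either
#' goal, while above both goals the fitness grows linearly.
#'
#' @param accuracy,recall Fractions in `[0, 1]`.
#' @param thresholds A [fitness_thresholds()] list.
#' @param penalty_coef,penalty_exp Penalty shape (defaults 1.3 and 3/2).
#' @return Scalar fitness value.
#' @export
ga_fitness <- function(accuracy, recall, thresholds = fitness_thresholds(),
                       penalty_coef = 1.3, penalty_exp = 1.5) {
  stopifnot(accuracy >= 0, accuracy <= 1, recall >= 0, recall <= 1)
  comp <- function(v) if (v >= 0) v else -penalty_coef * abs(v)^penalty_exp
  comp(100 * accuracy - thresholds$th_a) +
    comp(100 * recall - thresholds$th_r)
}

#' Correlation-filter scan over feature counts and thresholds
#'
#' The three-step correlation filter: rank features by `|r|` against the
#' class, then for each feature count `n` in the grid evaluate the top-`n`
#' mask with repeated stratified splits across the decision-threshold grid.
#' The best row is the one meeting both goals with maximal accuracy, or,
#' when no row meets them, the one with maximal penalised fitness.
#'
#' @param X Normalised feature matrix.
#' @param y Binary labels 0/1.
#' @param spec A [classifier_spec].
#' @param n_grid Feature counts to try.
#' @param threshold_grid Decision thresholds to try.
#' @param thresholds Goal [fitness_thresholds()] used to pick the best row.
#' @param repeats,test_fraction,seed Split protocol (see [evaluate_mask()]).
#' @return List with `table` (one row per grid cell: `n`, `threshold`,
#'   `accuracy`, `recall`, `fitness`), `best` (the selected row) and
#'   `profile` (the correlation vector).
#' @export
ccf_scan <- function(X, y, spec = classifier_spec("RF"),
                     n_grid = c(12, 24, 36, 48, 60, 78),
                     threshold_grid = seq(0, 1, by = 0.1),
                     thresholds = fitness_thresholds(),
                     repeats = 5L, test_fraction = 0.25, seed = 1L) {
  if (!length(n_grid) || !length(threshold_grid)) stop("empty grid")
  profile <- pearson_profile(X, y)
  rows <- vector("list", length(n_grid))
  for (i in seq_along(n_grid)) {
    mask <- top_n_mask(profile, n_grid[i])
    sc <- threshold_scan(mask, spec, X, y, threshold_grid, repeats,
                         test_fraction, seed)
    rows[[i]] <- cbind(n = n_grid[i], sc)
  }
  tab <- do.call(rbind, rows)
  tab$fitness <- mapply(function(a, r) ga_fitness(a / 100, r / 100,
                                                  thresholds),
                        tab$accuracy, tab$recall)
  ok <- tab$accuracy >= thresholds$th_a & tab$recall >= thresholds$th_r
  best <- if (any(ok)) {
    cand <- tab[ok, ]
    cand[order(-cand$accuracy, -cand$recall)[1L], ]
  } else tab[which.max(tab$fitness), ]
  list(table = tab, best = best, profile = profile)
}

#' GA configuration
#'
#' Defaults follow the wrapper-selection setup: population 400, 200 parents
#' by size-5 tournament, single-point crossover, 2.5% per-gene mutation,
#' offspring-only replacement, 60 generations (the method is typically run
#' for 50–70).
#'
#' @param population Population size.
#' @param parents Number of parents selected per generation.
#' @param tournament_size Tournament size.
#' @param mutation_rate Per-gene bit-flip probability.
#' @param generations Number of generations.
#' @param thresholds Goal [fitness_thresholds()].
#' @param seed Integer seed.
#' @param test_fraction Held-out fraction of the single evaluation split.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population = 400L, parents = 200L,
                      tournament_size = 5L, mutation_rate = 0.025,
                      generations = 60L,
                      thresholds = fitness_thresholds(), seed = 1L,
                      test_fraction = 0.25) {
  stopifnot(population >= 2L, parents >= 2L, parents <= population,
            tournament_size >= 1L, mutation_rate >= 0, mutation_rate <= 1,
            generations >= 1L)
  structure(list(population = as.integer(population),
                 parents = as.integer(parents),
                 tournament_size = as.integer(tournament_size),
                 mutation_rate = mutation_rate,
                 generations = as.integer(generations),
                 thresholds = thresholds, seed = as.integer(seed),
                 test_fraction = test_fraction),
            class = "ga_config")
}

#' Wrapper genetic-algorithm feature selection
#'
#' Chromosomes are binary masks of length `ncol(X)` (gene 1 selects the
#' feature). Each generation: fitnesses are computed, `parents` chromosomes
#' are chosen by size-`tournament_size` tournaments, offspring are produced
#' by single-point crossover of parent pairs, every gene mutates
#' independently with probability `mutation_rate`, and the offspring replace
#' the population entirely. The best-ever chromosome is tracked outside the
#' population and returned.
#'
#' By default a chromosome's fitness is the penalised [ga_fitness()] of a
#' classifier trained on one fixed stratified split drawn at the start of
#' the run — deterministic per mask, so fitnesses are cached. All-zero
#' chromosomes get a sentinel fitness of `-1e6`. A custom
#' `fitness_fn(mask)` can replace the wrapper evaluation (e.g. for planted
#' benchmarks).
#'
#' @param X Normalised feature matrix.
#' @param y Binary labels 0/1.
#' @param spec A [classifier_spec] used as the fitness evaluator.
#' @param threshold Decision threshold used inside the fitness evaluation.
#' @param config A [ga_config()].
#' @param fitness_fn Optional function(mask) -> scalar overriding the
#'   wrapper fitness.
#' @return An object of class `ga_run`: `best_mask`, `best_fitness`,
#'   `history` (per-generation best / mean / best-so-far) and `evaluations`
#'   (count of distinct mask evaluations).
#' @export
ga_select <- function(X, y, spec = classifier_spec("RF"), threshold = 0.5,
                      config = ga_config(), fitness_fn = NULL) {
  stopifnot(inherits(config, "ga_config"))
  set.seed(config$seed)
  n_genes <- ncol(X)
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L

  if (is.null(fitness_fn)) {
    tr <- stratified_train_idx(y, config$test_fraction)
    fit_seed <- sample.int(.Machine$integer.max, 1L)
    fitness_fn <- function(mask) {
      model <- train_classifier(spec, X[tr, mask == 1L, drop = FALSE],
                                y[tr], fit_seed)
      pred <- predict_with_threshold(model, X[-tr, mask == 1L, drop = FALSE],
                                     threshold)
      m <- cm_metrics(confusion(y[-tr], pred))
      ga_fitness(m$accuracy, m$recall, config$thresholds)
    }
  }

  eval_mask <- function(mask) {
    if (sum(mask) == 0L) return(-1e6)
    key <- paste(mask, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_eval <<- n_eval + 1L
    cache[[key]] <- fitness_fn(mask)
  }

  pop <- matrix(as.integer(stats::runif(config$population * n_genes) < 0.5),
                config$population, n_genes)
  best_mask <- NULL
  best_fit <- -Inf
  hist <- data.frame(generation = seq_len(config$generations),
                     best = NA_real_, mean = NA_real_,
                     best_so_far = NA_real_)

  for (g in seq_len(config$generations)) {
    fits <- apply(pop, 1L, eval_mask)
    gb <- which.max(fits)
    if (fits[gb] > best_fit) {
      best_fit <- fits[gb]
      best_mask <- pop[gb, ]
    }
    hist$best[g] <- fits[gb]
    hist$mean[g] <- mean(fits)
    hist$best_so_far[g] <- best_fit
    if (g == config$generations) break
    # size-k tournaments on fitness
    parents <- pop[vapply(seq_len(config$parents), function(i) {
      cand <- sample.int(config$population, config$tournament_size)
      cand[which.max(fits[cand])]
    }, integer(1)), , drop = FALSE]
    # single-point crossover of random parent pairs; offspring-only
    # replacement (no elitism inside the population)
    offspring <- matrix(0L, config$population, n_genes)
    for (j in seq_len(ceiling(config$population / 2))) {
      pair <- sample.int(config$parents, 2L)
      cp <- sample.int(n_genes - 1L, 1L)
      kids <- single_point_cross(parents[pair[1L], ], parents[pair[2L], ], cp)
      offspring[2L * j - 1L, ] <- kids[[1L]]
      if (2L * j <= config$population) offspring[2L * j, ] <- kids[[2L]]
    }
    if (config$mutation_rate > 0) {
      flip <- matrix(stats::runif(length(offspring)) < config$mutation_rate,
                     nrow(offspring))
      offspring[flip] <- 1L - offspring[flip]
    }
    pop <- offspring
  }

  structure(list(best_mask = best_mask, best_fitness = best_fit,
                 history = hist, evaluations = n_eval),
            class = "ga_run")
}

# exchange gene tails after position cp; identical parents are a fixed point
single_point_cross <- function(p1, p2, cp) {
  n <- length(p1)
  list(c(p1[seq_len(cp)], p2[(cp + 1L):n]),
       c(p2[seq_len(cp)], p1[(cp + 1L):n]))
}

#' @export
print.ga_run <- function(x, ...) {
  cat(sprintf(
    "<ga_run: %d generations, best fitness %.4g, %d genes selected, %d evaluations>\n",
    nrow(x$history), x$best_fitness, sum(x$best_mask), x$evaluations))
  invisible(x)
}

#' Save / load a selection mask as a JSON array
#'
#' @param mask Integer 0/1 vector.
#' @param path File path.
#' @return `path` (save) or the integer mask (load).
#' @export
save_mask <- function(mask, path) {
  jsonlite::write_json(as.integer(mask), path, digits = NA)
  invisible(path)
}

#' @rdname save_mask
#' @export
load_mask <- function(path) as.integer(jsonlite::fromJSON(path))
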
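#' @title Wrapper feature selection
#' @description Feature subsets are encoded as bitstrings (`1` keeps a
#'   feature, `0` drops it) and scored by the classification accuracy the
#'   subset achieves under the configured validation scheme. Two search
#'   strategies are provided: exhaustive enumeration of all `2^n - 1`
#'   non-empty subsets (tractable for the 10-feature blocks) and a genetic
#'   algorithm for the 20-feature combined block.
#' @name selection
NULL

bits_key <- function(bits) paste(as.integer(bits), collapse = "")

#' Build a memoized fitness evaluator
#'
#' Wraps a scoring function into an evaluator that caches results by subset
#' bitstring, so that repeated subsets (frequent in a converging genetic
#' population) are scored once. The canonical scorer is classification
#' accuracy of an assembled matrix restricted to the subset's columns under
#' six-fold cross-validation (see [subset_cv_evaluator()]), but any
#' deterministic `function(subset_indices) -> accuracy in [0, 1]` can be
#' wrapped, e.g. a lookup table in tests.
#'
#' @param score_fn Function taking an integer vector of (1-based) feature
#'   indices and returning a scalar accuracy in `[0, 1]`.
#' @param n_features Number of features the bitstrings range over.
#' @return An object of class `fitness_evaluator` with fields `evaluate`
#'   (function of a bit vector or index vector), `n_features`, `n_calls()`
#'   (underlying, uncached evaluations) and `cache_size()`.
#' @export
make_evaluator <- function(score_fn, n_features) {
  stopifnot(is.function(score_fn), n_features >= 1)
  cache <- new.env(parent = emptyenv())
  calls <- 0L
  to_bits <- function(subset) {
    # a full-length 0/1 vector is taken as a bitstring; anything else as
    # 1-based feature indices (the two readings agree where they overlap)
    if (length(subset) == n_features && all(subset %in% c(0, 1)))
      return(as.integer(subset))
    if (any(subset < 1 | subset > n_features))
      stop("subset indices out of range")
    b <- integer(n_features)
    b[as.integer(subset)] <- 1L
    b
  }
  evaluate <- function(subset) {
    bits <- to_bits(subset)
    if (!any(bits == 1L)) stop("empty subset is not a valid candidate")
    key <- bits_key(bits)
    if (!is.null(cache[[key]])) return(cache[[key]])
    calls <<- calls + 1L
    val <- score_fn(which(bits == 1L))
    if (!is.finite(val) || val < 0 || val > 1)
      stop("score_fn must return an accuracy in [0, 1]")
    cache[[key]] <- val
    val
  }
  structure(
    list(evaluate = evaluate, n_features = n_features,
         n_calls = function() calls,
         cache_size = function() length(ls(cache))),
    class = "fitness_evaluator"
  )
}

#' Evaluate one feature subset
#' @param evaluator A `fitness_evaluator`.
#' @param subset Integer vector of feature indices, or a full bit vector.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_subset <- function(evaluator, subset) {
  stopifnot(inherits(evaluator, "fitness_evaluator"))
  evaluator$evaluate(subset)
}

#' Cross-validated accuracy evaluator over an assembled matrix
#'
#' The canonical wrapper-selection fitness: restrict the matrix to a column
#' subset, then score with segment-fold six-fold cross-validation (or
#' resubstitution) using the one-against-all RBF SVM.
#'
#' @param matrix_df Assembled matrix from [assemble_matrix()].
#' @param config Classifier configuration from [svm_config()].
#' @param scheme `"sixfold"` (default) or `"resubstitution"`.
#' @return A memoized `fitness_evaluator` over the matrix's features.
#' @export
subset_cv_evaluator <- function(matrix_df, config = svm_config(),
                                scheme = c("sixfold", "resubstitution")) {
  scheme <- match.arg(scheme)
  fcols <- feature_columns(matrix_df)
  x <- as.matrix(matrix_df[, fcols, drop = FALSE])
  y <- factor(matrix_df$label)
  folds <- make_folds(matrix_df)
  score_fn <- function(idx) {
    xs <- x[, idx, drop = FALSE]
    if (scheme == "sixfold")
      kfold_cv_accuracy(xs, y, folds, config)$mean
    else
      resubstitution_accuracy(xs, y, config)
  }
  make_evaluator(score_fn, length(fcols))
}

popcount <- function(key) sum(strsplit(key, "")[[1]] == "1")

#' Exhaustive search over all non-empty feature subsets
#'
#' Evaluates every one of the `2^n - 1` non-empty subsets exactly once and
#' returns the accuracy argmax. Ties favor the smaller subset, then the
#' lexicographically smallest bitstring.
#'
#' @param evaluator A `fitness_evaluator`.
#' @param n_features Number of features; guarded at 20 (the enumeration
#'   doubles per feature).
#' @return List with `subset` (indices), `bits`, `fitness`, and `log`
#'   (data.frame of every bitstring with its fitness).
#' @export
full_search <- function(evaluator, n_features = evaluator$n_features) {
  stopifnot(inherits(evaluator, "fitness_evaluator"))
  if (n_features > 20)
    stop("full_search refused for n_features > 20 (2^n blows up); use ga_select")
  n_sub <- 2L^n_features - 1L
  keys <- character(n_sub)
  fitness <- numeric(n_sub)
  sizes <- integer(n_sub)
  for (m in seq_len(n_sub)) {
    bits <- as.integer(intToBits(m)[seq_len(n_features)])
    keys[m] <- bits_key(bits)
    sizes[m] <- sum(bits)
    fitness[m] <- evaluator$evaluate(bits)
  }
  ord <- order(-fitness, sizes, keys)
  best <- ord[1]
  best_bits <- as.integer(strsplit(keys[best], "")[[1]])
  list(subset = which(best_bits == 1L), bits = best_bits,
       fitness = fitness[best],
       log = data.frame(bits = keys, size = sizes, fitness = fitness,
                        stringsAsFactors = FALSE))
}

#' Genetic algorithm configuration
#'
#' Defaults follow common wrapper-GA practice: population 50, at most 100
#' generations, one-point crossover with probability 0.8, per-bit mutation
#' probability `1/n`, one elite copied unchanged per generation, and early
#' stopping when the best fitness has not improved for 20 generations.
#'
#' @param population_size >= 2.
#' @param n_generations Maximum generations.
#' @param crossover_prob Probability of one-point crossover per pair.
#' @param mutation_prob Per-bit flip probability; `NULL` means `1/n`.
#' @param elitism_count Number of top chromosomes copied unchanged.
#' @param early_stop_patience Generations without improvement before stopping.
#' @param seed Optional integer seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 50, n_generations = 100,
                      crossover_prob = 0.8, mutation_prob = NULL,
                      elitism_count = 1, early_stop_patience = 20,
                      seed = NULL) {
  if (population_size < 2) stop("population_size must be >= 2")
  for (p in c(crossover_prob, mutation_prob))
    if (!is.null(p) && (p < 0 || p > 1))
      stop("probabilities must lie in [0, 1]")
  if (elitism_count < 0 || elitism_count >= population_size)
    stop("elitism_count must be in [0, population_size)")
  structure(list(population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 elitism_count = as.integer(elitism_count),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = seed),
            class = "ga_config")
}

mutate_bits <- function(bits, pm) {
  flip <- stats::runif(length(bits)) < pm
  out <- as.integer(xor(bits == 1L, flip))
  # an all-zero chromosome is not a valid candidate: re-mutate until non-empty
  while (!any(out == 1L)) {
    flip <- stats::runif(length(out)) < max(pm, 1 / length(out))
    out <- as.integer(xor(out == 1L, flip))
  }
  out
}

#' Genetic-algorithm feature selection
#'
#' Chromosomes are feature bitstrings; fitness is the evaluator's accuracy.
#' Each generation: fitness-proportional (roulette) parent selection on
#' min-max-scaled fitness, one-point crossover, per-bit mutation (all-zero
#' offspring are re-mutated until non-empty), and copying of the
#' `elitism_count` best chromosomes unchanged. Evolution stops at
#' `n_generations` or when the best fitness has been flat for
#' `early_stop_patience` generations. With at least one elite, the best-so-far
#' fitness is non-decreasing across generations.
#'
#' @param evaluator A `fitness_evaluator`.
#' @param n_features Bitstring length.
#' @param config A [ga_config()].
#' @return List with `subset`, `bits`, `fitness`, `generations` run, and
#'   `log` (per-generation best/mean fitness and best bitstring).
#' @export
ga_select <- function(evaluator, n_features = evaluator$n_features,
                      config = ga_config()) {
  stopifnot(inherits(evaluator, "fitness_evaluator"),
            inherits(config, "ga_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- n_features
  pm <- if (is.null(config$mutation_prob)) 1 / n else config$mutation_prob
  ps <- config$population_size

  pop <- lapply(seq_len(ps), function(i) {
    b <- as.integer(stats::runif(n) < 0.5)
    if (!any(b == 1L)) b[sample.int(n, 1L)] <- 1L
    b
  })
  fit <- vapply(pop, evaluator$evaluate, numeric(1))

  best_bits <- pop[[which.max(fit)]]
  best_fit <- max(fit)
  stall <- 0L
  log <- vector("list", config$n_generations + 1L)
  log[[1]] <- data.frame(generation = 0L, best = best_fit,
                         mean = mean(fit), best_bits = bits_key(best_bits),
                         stringsAsFactors = FALSE)
  gens <- 0L
  for (g in seq_len(config$n_generations)) {
    gens <- g
    # roulette weights on min-max scaled fitness
    rng <- range(fit)
    w <- if (diff(rng) == 0) rep(1, ps) else
      (fit - rng[1]) / diff(rng) + 1e-6
    elite_idx <- order(-fit)[seq_len(config$elitism_count)]
    nxt <- pop[elite_idx]
    while (length(nxt) < ps) {
      par <- sample.int(ps, 2L, replace = TRUE, prob = w)
      c1 <- pop[[par[1]]]; c2 <- pop[[par[2]]]
      if (stats::runif(1) < config$crossover_prob && n >= 2) {
        cut <- sample.int(n - 1L, 1L)
        tmp <- c(c1[seq_len(cut)], c2[(cut + 1L):n])
        c2 <- c(c2[seq_len(cut)], c1[(cut + 1L):n])
        c1 <- tmp
      }
      nxt[[length(nxt) + 1L]] <- mutate_bits(c1, pm)
      if (length(nxt) < ps) nxt[[length(nxt) + 1L]] <- mutate_bits(c2, pm)
    }
    pop <- nxt
    fit <- vapply(pop, evaluator$evaluate, numeric(1))
    gen_best <- max(fit)
    if (gen_best > best_fit + 1e-12) {
      best_fit <- gen_best
      best_bits <- pop[[which.max(fit)]]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    log[[g + 1L]] <- data.frame(generation = g, best = best_fit,
                                mean = mean(fit),
                                best_bits = bits_key(best_bits),
                                stringsAsFactors = FALSE)
    if (stall >= config$early_stop_patience) break
  }
  list(subset = which(best_bits == 1L), bits = best_bits, fitness = best_fit,
       generations = gens,
       log = do.call(rbind, log[!vapply(log, is.null, logical(1))]))
}
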
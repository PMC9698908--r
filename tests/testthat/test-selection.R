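test_that("the evaluator memoizes and rejects empty subsets", {
  calls <- 0
  ev <- make_evaluator(function(idx) {
    calls <<- calls + 1
    length(idx) / 4
  }, 4)
  expect_equal(evaluate_subset(ev, c(1, 3)), 0.5)
  expect_equal(evaluate_subset(ev, c(1, 3)), 0.5)
  expect_equal(evaluate_subset(ev, c(1L, 0L, 1L, 0L)), 0.5)  # bit form
  expect_equal(calls, 1)  # one underlying evaluation for all three calls
  expect_equal(ev$n_calls(), 1)
  expect_error(evaluate_subset(ev, integer(0)), "empty subset")
  expect_error(evaluate_subset(ev, c(0L, 0L, 0L, 0L)), "empty subset")
})

test_that("full search enumerates every non-empty subset exactly once", {
  ev1 <- make_evaluator(function(idx) 1, 1)
  r1 <- full_search(ev1)
  expect_equal(ev1$n_calls(), 1)
  expect_equal(r1$subset, 1L)

  f <- lookup_score_fn(3, n = 4)
  ev4 <- make_evaluator(f, 4)
  r4 <- full_search(ev4)
  expect_equal(ev4$n_calls(), 2^4 - 1)
  oracle <- lookup_argmax(f, n = 4)
  expect_equal(r4$subset, oracle$subset)
  expect_equal(r4$fitness, oracle$fitness)

  ev10 <- make_evaluator(lookup_score_fn(5, n = 10), 10)
  r10 <- full_search(ev10)
  expect_equal(ev10$n_calls(), 1023)
  expect_equal(nrow(r10$log), 1023)

  expect_error(full_search(make_evaluator(function(i) 0.5, 21)),
               "n_features > 20")
})

test_that("full-search ties favor smaller subsets then lexicographic order", {
  # constant fitness: everything ties; the winner must be the single-feature
  # subset with the lexicographically smallest bitstring, i.e. {3} = 001
  ev <- make_evaluator(function(idx) 0.5, 3)
  r <- full_search(ev)
  expect_equal(sum(r$bits), 1)
  expect_equal(r$bits, c(0L, 0L, 1L))
})

test_that("the genetic algorithm climbs monotone fitness to the full set", {
  ev <- make_evaluator(function(idx) length(idx) / 8, 8)
  r <- ga_select(ev, config = ga_config(population_size = 30,
                                        n_generations = 60,
                                        early_stop_patience = 60, seed = 2))
  expect_equal(r$bits, rep(1L, 8))
  expect_equal(r$fitness, 1)
})

test_that("with elitism the best-so-far fitness never decreases", {
  ev <- make_evaluator(lookup_score_fn(11, n = 10), 10)
  r <- ga_select(ev, config = ga_config(seed = 31))
  expect_true(all(diff(r$log$best) >= 0))
  expect_equal(r$fitness, max(r$log$best))
})

test_that("the genetic algorithm finds the full-search optimum", {
  hits <- 0
  for (s in 1:5) {
    f <- lookup_score_fn(s, n = 10)
    oracle <- full_search(make_evaluator(f, 10))
    ga <- ga_select(make_evaluator(f, 10),
                    config = ga_config(seed = 100 + s))
    if (identical(ga$subset, oracle$subset)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("GA configuration is validated", {
  expect_error(ga_config(population_size = 1), "population_size")
  expect_error(ga_config(crossover_prob = 1.4), "probabilities")
  expect_error(ga_config(elitism_count = 50, population_size = 50),
               "elitism_count")
})
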
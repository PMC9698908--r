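# fixtures are generated in code and cached for the session: building a
# cohort once and sharing it keeps the suite fast without touching disk

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# beat-level (truth-table) feature set of a small cohort: classifier and
# featurization tests do not need waveform rendering
small_cohort_features <- function() {
  fixture("small_feats", function() {
    coh <- synthesize_cohort(n_subjects = 10, seed = 404, render = FALSE)
    featurize_cohort(delineate_cohort(coh, use_truth = TRUE))
  })
}

# full-size rendered cohort at the default study conditions (43 subjects,
# five stages, 3-min records at 1024 Hz with default noise), delineated
# through the signal-level pipeline
default_cohort <- function() {
  fixture("default_cohort", function() synthesize_cohort(seed = 101))
}

default_cohort_beats <- function() {
  fixture("default_beats", function() delineate_cohort(default_cohort()))
}

default_cohort_features <- function() {
  fixture("default_feats", function() featurize_cohort(default_cohort_beats()))
}

# structured lookup-table fitness with a unique optimum: a hamming-distance
# gradient toward a hidden target plus bounded rugged noise
lookup_score_fn <- function(seed, n = 10, noise = 0.3) {
  set.seed(seed)
  target <- as.integer(stats::runif(n) < 0.5)
  if (!any(target == 1L)) target[1] <- 1L
  eps <- stats::runif(2^n - 1) * noise
  function(idx) {
    b <- integer(n)
    b[idx] <- 1L
    (1 - noise) * (1 - sum(b != target) / n) + eps[sum(b * 2^(seq_len(n) - 1))]
  }
}

# independent enumeration of a lookup problem's optimum (the oracle full
# search is checked against): direct loop over all subset codes
lookup_argmax <- function(score_fn, n = 10) {
  best <- -Inf
  best_idx <- NULL
  for (m in seq_len(2^n - 1)) {
    idx <- which(as.integer(intToBits(m)[seq_len(n)]) == 1L)
    v <- score_fn(idx)
    if (v > best) {
      best <- v
      best_idx <- idx
    }
  }
  list(subset = best_idx, fitness = best)
}

expect_within_3se <- function(values, target, label) {
  se <- stats::sd(values) / sqrt(length(values))
  expect_lt(abs(mean(values) - target), 3 * se,
            label = sprintf("%s: |%.3f - %.3f| vs 3*SE %.3f",
                            label, mean(values), target, 3 * se))
}
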
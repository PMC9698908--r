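make_beats <- function(st, dt, bva, onset = NULL) {
  n <- length(st)
  vvi <- st + dt
  if (is.null(onset)) onset <- c(0, cumsum(vvi[-n])) / 1000
  data.frame(beat_idx = seq_len(n), onset_s = onset,
             peak_s = onset + st / 1000, end_s = onset + vvi / 1000,
             bva_mV = bva, st_ms = st, dt_ms = dt,
             ppi_ms = c(diff(onset + st / 1000) * 1000, NA), vvi_ms = vvi)
}

test_that("segmentation partitions beats into half-open 30 s windows", {
  b <- make_beats(rep(200, 220), rep(650, 220), rep(10, 220))
  sb <- segment_beats(b, duration_s = 180, window_s = 30)
  expect_equal(sort(unique(sb$segment_idx)), 1:6)
  # partition: every retained beat appears exactly once
  expect_equal(nrow(sb), sum(b$onset_s < 180))
  expect_false(anyDuplicated(sb$beat_idx) > 0)
  # a beat with onset exactly at 30.0 s belongs to segment 2
  b2 <- make_beats(rep(200, 3), rep(650, 3), rep(10, 3),
                   onset = c(29.15, 30.0, 30.85))
  sb2 <- segment_beats(b2, duration_s = 60, window_s = 30)
  expect_equal(sb2$segment_idx, c(1L, 2L, 2L))
  expect_warning(segment_beats(b, duration_s = 185, window_s = 30),
                 "partial window")
})

test_that("segment features are the mean and population SD of each index", {
  # identical beats: means equal the beat values, all STDs zero
  b <- make_beats(rep(200, 5), rep(650, 5), rep(10, 5))
  f <- segment_features(b)
  expect_length(f, 10)
  expect_named(f, waveform_feature_names())
  expect_equal(unname(f["st_mean"]), 200)
  expect_equal(unname(f[c("bva_std", "st_std", "dt_std", "vvi_std")]),
               rep(0, 4))
  # hand-computed population SD (divisor n) for st = {190, 200, 210}
  b3 <- make_beats(c(190, 200, 210), rep(650, 3), rep(10, 3))
  f3 <- segment_features(b3)
  expect_equal(unname(f3["st_mean"]), 200)
  expect_equal(unname(f3["st_std"]), sqrt(((-10)^2 + 0 + 10^2) / 3))
  # the final beat's undefined PPI is excluded pairwise
  expect_equal(unname(f3["ppi_mean"]), mean(b3$ppi_ms[1:2]))
  expect_error(segment_features(b3[1:2, ]), "fewer than 3")
})

test_that("baseline reference averages a subject's baseline segments", {
  f <- small_cohort_features()
  one <- f[f$subject_id == f$subject_id[1] & f$stage == "baseline", ]
  ref <- baseline_reference(one)
  expect_equal(unname(ref["st_mean"]), mean(one$st_mean))
  # identical segments: the reference equals any one of them
  two <- one[c(1, 1), ]
  expect_equal(baseline_reference(two),
               unlist(one[1, waveform_feature_names()]))
  # hand-built two-segment case: elementwise average
  expect_equal(unname(baseline_reference(one[1:2, ])["bva_mean"]),
               mean(one$bva_mean[1:2]))
})

test_that("differential features subtract the baseline reference", {
  ref <- setNames(as.numeric(1:10), waveform_feature_names())
  state <- ref + 5
  d <- differential_features(state, ref)
  expect_named(d, waveform_feature_names(differential = TRUE))
  expect_equal(unname(d), rep(5, 10))
  # a state equal to its reference maps to the zero vector
  expect_equal(unname(differential_features(ref, ref)), rep(0, 10))
  bad <- setNames(as.numeric(1:10), paste0("x", 1:10))
  expect_error(differential_features(bad, ref), "mismatch")
})

test_that("assembled matrices have the declared shape and labels", {
  f <- small_cohort_features()
  n_subj <- length(unique(f$subject_id))

  m10 <- assemble_matrix(f, "waveform10", "4C")
  expect_length(feature_columns(m10), 10)
  m20 <- assemble_matrix(f, "combined20", "4C")
  expect_length(feature_columns(m20), 20)
  # four recall stages x six segments per subject; baseline rows excluded
  expect_equal(nrow(m20), n_subj * 4 * 6)
  expect_false("baseline" %in% m20$stage)

  m2c <- assemble_matrix(f, "waveform10", "2C")
  expect_setequal(unique(m2c$label), c("negative", "positive"))
  expect_setequal(m2c$stage[m2c$label == "negative"], c("anger", "sadness"))
  expect_setequal(m2c$stage[m2c$label == "positive"],
                  c("neutral", "happiness"))
  m3c <- assemble_matrix(f, "differential10", "3C")
  expect_setequal(unique(m3c$label), c("negative", "neutral", "positive"))
  expect_setequal(m3c$stage[m3c$label == "positive"], "happiness")

  mb <- assemble_matrix(f, "combined20", "baseline_vs_anger")
  expect_setequal(unique(mb$stage), c("baseline", "anger"))
  expect_setequal(unique(mb$label), c("baseline", "state"))

  # per-subject mean of baseline differential rows is zero by construction
  base_d <- mb[mb$stage == "baseline", ]
  per_subj <- tapply(base_d$d_st_mean, base_d$subject_id, mean)
  expect_equal(as.numeric(per_subj), rep(0, n_subj), tolerance = 1e-10)

  # assembly is deterministic
  expect_identical(m20, assemble_matrix(f, "combined20", "4C"))
  expect_error(assemble_matrix(f, "waveform10", "5C"), "unknown task")

  # segment-matched pairing: baseline rows difference out to exactly zero
  mbm <- assemble_matrix(f, "combined20", "baseline_vs_anger",
                         diff_pairing = "matched")
  base_rows <- mbm[mbm$stage == "baseline", ]
  expect_equal(max(abs(as.matrix(
    base_rows[, waveform_feature_names(TRUE)]))), 0)
})

test_that("z-score normalization is exact and leakage-free", {
  set.seed(99)
  train <- matrix(rnorm(60, 5, 3), ncol = 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  zm <- zscore_fit(train)
  z <- zscore_apply(zm, train)
  expect_equal(unname(colMeans(z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 3), tolerance = 1e-12)

  # hand-computed 3 x 2 case
  h <- matrix(c(1, 2, 3, 10, 20, 30), ncol = 2)
  zh <- zscore_apply(zscore_fit(h), h)
  expect_equal(zh[, 1], c(-1, 0, 1))
  expect_equal(zh[, 2], c(-1, 0, 1))

  # leakage guard: the fitted model must not depend on test rows
  test_a <- matrix(rnorm(30, 100, 50), ncol = 3)
  test_b <- matrix(rnorm(30, -7, 0.1), ncol = 3)
  expect_identical(zm$center, zscore_fit(train)$center)
  za <- zscore_apply(zm, test_a)
  expect_identical(zm$center, zscore_fit(train)$center)
  expect_equal(zscore_apply(zm, test_b),
               sweep(sweep(test_b, 2, zm$center), 2, zm$scale, "/"))

  # constant column: transformed to zero, with a warning
  cc <- cbind(x = c(1, 1, 1), y = c(1, 2, 3))
  expect_warning(zc <- zscore_apply(zscore_fit(cc), cc), "constant")
  expect_equal(unname(zc[, 1]), rep(0, 3))
  expect_error(zscore_fit(cc[1, , drop = FALSE]), "at least 2")
})
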
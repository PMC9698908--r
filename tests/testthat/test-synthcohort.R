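test_that("reference stage parameters satisfy the morphological invariants", {
  sp <- default_stage_params()
  expect_setequal(sp$stage, ppg_stages())
  expect_true(all(sp[, c("bva_mean", "st_mean", "dt_mean")] > 0))
  expect_true(all(sp[, c("bva_sd", "st_sd", "dt_sd")] >= 0))
  # systolic upstroke is always faster than the diastolic decay
  expect_true(all(sp$st_mean < sp$dt_mean))
  # baseline column sanity
  b <- sp[sp$stage == "baseline", ]
  expect_equal(b$st_mean, 196.01)
  expect_equal(b$dt_mean, 650.84)
  expect_equal(b$bva_mean, 11.82)
})

test_that("subject random effects have the configured scale and determinism", {
  sp <- default_stage_params()
  # zero between-subject fraction: every subject sits at the population mean
  s0 <- sample_subject_params(sp, between_sd_fraction = 0, seed = 11)
  expect_equal(s0$stages$st_mean, sp$st_mean)
  expect_equal(s0$stages$st_sd, sp$st_sd)

  # determinism: same seed, same realization
  a <- sample_subject_params(sp, 0.6, "S1", seed = 42)
  b <- sample_subject_params(sp, 0.6, "S1", seed = 42)
  expect_identical(a$stages, b$stages)

  expect_error(sample_subject_params(sp, between_sd_fraction = 1.2),
               "between_sd_fraction")

  # Monte-Carlo: the SD of baseline ST offsets across many subjects matches
  # the configured between-subject scale 0.6 * 50.12 ms
  offs <- vapply(seq_len(1000), function(i) {
    s <- sample_subject_params(sp, 0.6, seed = 1000 + i)
    s$stages$st_mean[1] - sp$st_mean[1]
  }, numeric(1))
  target_sd <- 0.6 * sp$st_sd[1]
  # SE of an SD estimate ~ sd / sqrt(2 n)
  se <- target_sd / sqrt(2 * length(offs))
  expect_lt(abs(sd(offs) - target_sd), 3 * se)
  # within-subject SD shrinks to sqrt(1 - 0.6^2) = 0.8 of the population SD
  s <- sample_subject_params(sp, 0.6, seed = 5)
  expect_equal(s$stages$st_sd, 0.8 * sp$st_sd)
})

test_that("fixed beat parameters produce exact deterministic beat trains", {
  p <- list(bva_mean = 10, bva_sd = 0, st_mean = 200, st_sd = 0,
            dt_mean = 650, dt_sd = 0)
  out <- synthesize_record(p, duration_s = 8.5, fs = 1000,
                           noise_sd = 0, wander_amp = 0, seed = 1)
  expect_equal(nrow(out$truth), 10)          # 10 x 0.85 s fills 8.5 s exactly
  expect_equal(out$truth$bva_mV, rep(10, 10))
  expect_equal(out$truth$vvi_ms, rep(850, 10))
  # every peak sample is exactly BVA above the valley level (0)
  pk <- round(out$truth$peak_s * 1000) + 1
  expect_equal(out$record$samples[pk], rep(10, 10), tolerance = 1e-9)
  # zero-variance, zero-noise: strictly periodic with period st + dt
  x <- out$record$samples
  period <- 850
  expect_equal(x[seq_len(1000)], x[seq_len(1000) + period], tolerance = 1e-9)
})

test_that("drawn beats converge to the configured (truncated) stage means", {
  sp <- default_stage_params()[1, ]
  beats <- synthesize_beats(sp, n_beats = 10000, seed = 77)
  # law of large numbers against the closed-form truncated-normal mean
  trunc_mean <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  st_expect <- trunc_mean(196.01, 50.12, 80, 450)
  expect_within_3se(beats$st_ms, st_expect, "mean drawn ST")
  dt_expect <- trunc_mean(650.84, 82.39, 300, 1200)
  expect_within_3se(beats$dt_ms, dt_expect, "mean drawn DT")
  # truncation keeps the configured ST population mean within ~1.5 ms
  expect_lt(abs(st_expect - 196.01), 1.6)
  # internal consistency forced by construction
  expect_equal(beats$st_ms + beats$dt_ms, beats$vvi_ms)
  expect_true(all(beats$st_ms >= 80 & beats$st_ms <= 450))
  expect_true(all(beats$dt_ms >= 300 & beats$dt_ms <= 1200))
  expect_true(all(beats$bva_mV > 0))
})

test_that("record synthesis validates its arguments", {
  sp <- default_stage_params()[1, ]
  expect_error(synthesize_record(sp, duration_s = -1), "duration_s")
  expect_error(synthesize_record(sp, duration_s = 10, fs = 64), "fs")
  expect_error(synthesize_beats(sp), "n_beats or duration_s")
})

test_that("cohort generation is a pure function of configuration and seed", {
  coh1 <- synthesize_cohort(n_subjects = 3, duration_s = 20, fs = 256,
                            seed = 9)
  coh2 <- synthesize_cohort(n_subjects = 3, duration_s = 20, fs = 256,
                            seed = 9)
  expect_equal(nrow(coh1$manifest), 3 * 5)
  expect_identical(coh1$manifest, coh2$manifest)
  expect_identical(coh1$truths, coh2$truths)
  expect_identical(lapply(coh1$records, `[[`, "samples"),
                   lapply(coh2$records, `[[`, "samples"))
  # a different seed changes the signals
  coh3 <- synthesize_cohort(n_subjects = 3, duration_s = 20, fs = 256,
                            seed = 10)
  expect_false(identical(coh1$truths, coh3$truths))
  expect_error(synthesize_cohort(n_subjects = 2, subject_ids = c("A", "A")),
               "duplicate")
})

test_that("cohort round-trips through the plain-text interchange formats", {
  coh <- synthesize_cohort(n_subjects = 1, stages = "baseline",
                           duration_s = 10, fs = 256, seed = 3)
  dir <- withr::local_tempdir()
  man <- write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  rec <- read_ppg_csv(man$path[1], fs = 256)
  expect_equal(rec$samples, coh$records[[1]]$samples, tolerance = 1e-6)
  tt <- read_beats_tsv(file.path(dir, paste0(man$subject_id[1], ".",
                                             man$stage[1], ".truth.tsv")))
  expect_equal(tt$st_ms, coh$truths[[1]]$st_ms, tolerance = 1e-6)
})
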
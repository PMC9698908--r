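fs_test <- 1024

test_that("band-pass filter attenuates out-of-band and preserves in-band", {
  t <- (0:(fs_test * 20 - 1)) / fs_test
  x <- sin(2 * pi * 0.2 * t) + sin(2 * pi * 1.2 * t) + sin(2 * pi * 80 * t)
  y <- bandpass_filter(x, 0.1, 50, fs = fs_test)
  expect_length(y, length(x))
  amp_at <- function(v, f) {
    n <- length(v)
    sp <- abs(stats::fft(v)) / n * 2
    fr <- (0:(n - 1)) * fs_test / n
    sp[which.min(abs(fr - f))]
  }
  # 80 Hz lies an octave above the pass band: >= 20 dB down
  expect_lt(20 * log10(amp_at(y, 80) / amp_at(x, 80)), -20)
  # 1.2 Hz (a typical pulse fundamental) is preserved within 5%
  expect_gt(amp_at(y, 1.2) / amp_at(x, 1.2), 0.95)
  # filtering twice changes the pass-band content only marginally
  y2 <- bandpass_filter(y, 0.1, 50, fs = fs_test)
  expect_gt(amp_at(y2, 1.2) / amp_at(y, 1.2), 0.95)
  expect_error(bandpass_filter(x, 50, 0.1, fs = fs_test), "low_hz")
})

test_that("peak detection handles degenerate and exact cases", {
  expect_length(detect_peaks(rep(1, 1000), fs = fs_test), 0)
  # one triangular pulse: the unique apex
  tri <- c(seq(0, 1, length.out = 101), seq(1, 0, length.out = 101)[-1])
  expect_equal(detect_peaks(tri, fs = 201), 101)
})

test_that("valley tie-breaks take the earliest sample of a minimum plateau", {
  pulse <- c(seq(0, 1, length.out = 51), seq(1, 0, length.out = 51)[-1])
  x <- c(pulse, rep(0, 100), pulse)
  peaks <- detect_peaks(x, min_distance_s = 0.1, fs = 1000)
  expect_length(peaks, 2)
  valleys <- detect_valleys(x, peaks)
  # between-peak valley: the first sample of the zero plateau (the falling
  # edge of the first pulse touches zero one sample before the flat segment)
  expect_equal(valleys[2], 101L)
  expect_warning(v <- detect_valleys(x, peaks[1]), "fewer than 2")
  expect_length(v, 0)
})

test_that("beat indices follow the landmark definitions exactly", {
  # valley (0 s, 0 mV), peak (0.2 s, 11.82 mV), valley (0.85 s, 0 mV)
  fs <- 1000
  x <- numeric(1001)
  x[201] <- 11.82
  b <- delineate_beats(x, list(peaks = c(201L, 1001L),
                               valleys = c(1L, 851L)), fs = fs)
  expect_equal(nrow(b), 1)
  expect_equal(b$bva_mV, 11.82)
  expect_equal(b$st_ms, 200)
  expect_equal(b$dt_ms, 650)
  expect_equal(b$vvi_ms, 850)
  expect_true(is.na(b$ppi_ms))  # single complete beat: no next peak interval
  expect_error(
    delineate_beats(x, list(peaks = c(100L, 200L), valleys = c(150L, 850L)),
                    fs = fs),
    "non-alternating")
})

test_that("noiseless synthetic beats are recovered sample-accurately", {
  p <- default_stage_params()[1, ]
  out <- synthesize_record(p, duration_s = 30, fs = 1024,
                           noise_sd = 0, wander_amp = 0, seed = 12)
  b <- delineate_record(out$record, filter = "off")
  tr <- out$truth
  # every interior truth beat is found; edge beats may be dropped
  expect_gte(nrow(b), nrow(tr) - 2)
  m <- vapply(b$onset_s, function(v) which.min(abs(tr$onset_s - v)),
              integer(1))
  tol_s <- 1.5 / 1024  # one sample, plus rounding of the continuous onset
  expect_lt(max(abs(b$onset_s - tr$onset_s[m])), tol_s)
  expect_lt(max(abs(b$peak_s - tr$peak_s[m])), tol_s)
  expect_lt(max(abs(b$bva_mV - tr$bva_mV[m])), 0.01)
  # st + dt = vvi exactly, by construction of the indices
  expect_equal(b$st_ms + b$dt_ms, b$vvi_ms)
})

test_that("mean PPI and mean VVI agree on a long record", {
  p <- default_stage_params()[1, ]
  out <- synthesize_record(p, duration_s = 120, fs = 512,
                           noise_sd = 0, wander_amp = 0, seed = 8)
  b <- delineate_record(out$record, filter = "off")
  period <- mean(b$vvi_ms)
  expect_lt(abs(mean(b$ppi_ms, na.rm = TRUE) - period), period / nrow(b))
})

test_that("noisy-path delineation recovers beat morphology with small bias", {
  p <- default_stage_params()[1, ]
  out <- synthesize_record(p, duration_s = 180, fs = 1024,
                           noise_sd = 0.15, wander_amp = 0.3, seed = 7)
  b <- delineate_record(out$record, filter = "on")
  tr <- out$truth
  expect_gt(nrow(b), 0.9 * nrow(tr))
  m <- vapply(b$onset_s, function(v) which.min(abs(tr$onset_s - v)),
              integer(1))
  expect_lt(abs(mean(b$st_ms - tr$st_ms[m])), 5)    # ms
  expect_lt(abs(mean(b$dt_ms - tr$dt_ms[m])), 5)    # ms
  expect_lt(abs(mean(b$bva_mV - tr$bva_mV[m])), 0.1)  # mV
})
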
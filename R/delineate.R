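#' @title PPG pulse-wave delineation
#' @description Landmark detection (one systolic peak bounded by two valleys
#'   per beat) and computation of the five per-beat morphological indices:
#'   blood volume amplitude (BVA), systolic upstroke time (ST), diastolic time
#'   (DT), peak-to-peak interval (PPI) and valley-to-valley interval (VVI).
#' @name delineation
NULL

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth high-pass at `low_hz` and low-pass at
#' `high_hz`, each forward-backward (`signal::filtfilt`), so the pass band is
#' phase-neutral and landmark timing is not shifted. The cascade of two
#' first-stage filters is numerically better behaved than a single band-pass
#' design when `low_hz` is a tiny fraction of the Nyquist frequency, as it is
#' for the conventional 0.1--50 Hz PPG band.
#'
#' @param record A [ppg_record()] or a numeric vector (then `fs` is required).
#' @param low_hz,high_hz Band edges, `0 < low_hz < high_hz < fs/2`.
#' @param fs Sampling rate when `record` is a bare vector.
#' @param order Butterworth order per stage (default 3, giving > 20 dB
#'   power attenuation one octave beyond the band edge under filtfilt).
#' @return Same type as the input, filtered; length preserved.
#' @export
bandpass_filter <- function(record, low_hz = 0.1, high_hz = 50, fs = NULL,
                            order = 3) {
  is_rec <- inherits(record, "ppg_record")
  x <- if (is_rec) record$samples else as.numeric(record)
  if (is_rec) fs <- record$fs
  if (is.null(fs)) stop("fs required when record is a numeric vector")
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("need 0 < low_hz < high_hz < fs/2")
  hp <- signal::butter(order, low_hz / (fs / 2), type = "high")
  lp <- signal::butter(order, high_hz / (fs / 2), type = "low")
  y <- signal::filtfilt(hp, x)
  y <- signal::filtfilt(lp, y)
  if (is_rec) {
    record$samples <- y
    record
  } else y
}

# strict/plateau-aware local maxima; returns the first sample of a summit
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  dx <- diff(x)
  s <- sign(dx)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(integer(0))
  r <- s[nz]
  chg <- which(r[-length(r)] == 1 & r[-1] == -1)
  if (!length(chg)) return(integer(0))
  nz[chg] + 1L
}

# prominence of candidate maxima: height above the higher of the two bases,
# where each base is the signal minimum between the candidate and the nearest
# strictly higher point on that side (or the record edge)
peak_prominences <- function(x, cand) {
  k <- length(cand)
  if (k == 0L) return(numeric(0))
  h <- x[cand]
  bounds <- c(1L, cand, length(x))
  gap_min <- vapply(seq_len(k + 1L),
                    function(g) min(x[bounds[g]:bounds[g + 1L]]),
                    numeric(1))
  side_base <- function(ord, gaps) {
    # ord: candidate processing order; gaps[i] = min between predecessor and i
    base <- numeric(k)
    st_i <- integer(0); st_m <- numeric(0)
    for (i in ord) {
      cur <- gaps[i]
      while (length(st_i) && h[st_i[length(st_i)]] <= h[i]) {
        cur <- min(cur, st_m[length(st_m)])
        st_i <- st_i[-length(st_i)]
        st_m <- st_m[-length(st_m)]
      }
      base[i] <- cur
      st_i <- c(st_i, i); st_m <- c(st_m, cur)
    }
    base
  }
  lbase <- side_base(seq_len(k), gap_min[seq_len(k)])
  rbase <- side_base(rev(seq_len(k)), gap_min[seq_len(k) + 1L])
  h - pmax(lbase, rbase)
}

#' Detect systolic peaks in a PPG record
#'
#' Candidates are local maxima (the first sample of a flat summit). Two rules
#' reject implausible candidates: a prominence floor of
#' `min_prominence_frac` times the median candidate prominence, and a minimum
#' inter-peak spacing of `min_distance_s`. Spacing conflicts are resolved
#' greedily in favor of the higher-prominence candidate (ties: the earlier
#' one).
#'
#' @param record A [ppg_record()] or numeric vector (then `fs` required).
#' @param min_distance_s Minimum spacing between retained peaks, seconds.
#'   Default 0.33 s (about 180 beats/min).
#' @param min_prominence_frac Prominence floor as a fraction of the median
#'   candidate prominence. Default 0.3.
#' @param fs Sampling rate for bare vectors.
#' @return Sorted integer sample positions of retained peaks (possibly empty).
#' @export
detect_peaks <- function(record, min_distance_s = 0.33,
                         min_prominence_frac = 0.3, fs = NULL) {
  is_rec <- inherits(record, "ppg_record")
  x <- if (is_rec) record$samples else as.numeric(record)
  if (is_rec) fs <- record$fs
  if (is.null(fs)) stop("fs required when record is a numeric vector")
  if (!length(x)) stop("empty record")
  cand <- local_maxima(x)
  if (!length(cand)) return(integer(0))
  prom <- peak_prominences(x, cand)
  keep <- prom >= min_prominence_frac * stats::median(prom)
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(integer(0))
  min_dist <- round(min_distance_s * fs)
  ord <- order(-prom, cand)
  taken <- logical(length(cand))
  for (i in ord) {
    if (any(taken & abs(cand - cand[i]) < min_dist)) next
    taken[i] <- TRUE
  }
  sort(cand[taken])
}

#' Detect onset valleys between consecutive peaks
#'
#' One valley per consecutive-peak pair: the minimum of the signal strictly
#' between the two peaks (ties: earliest sample). Additionally the valley
#' preceding the first peak is the minimum between the record start and that
#' peak. With fewer than two peaks no between-peak valley exists and an empty
#' result is returned with a warning.
#'
#' @param record A [ppg_record()] or numeric vector.
#' @param peaks Sorted peak sample positions from [detect_peaks()].
#' @return Sorted integer sample positions of valleys (length = number of
#'   peaks when `length(peaks) >= 2`).
#' @export
detect_valleys <- function(record, peaks) {
  x <- if (inherits(record, "ppg_record")) record$samples else
    as.numeric(record)
  if (length(peaks) < 2L) {
    warning("fewer than 2 peaks; no between-peak valleys")
    return(integer(0))
  }
  pre_lo <- 1L
  pre_hi <- peaks[1] - 1L
  pre <- if (pre_hi >= pre_lo)
    pre_lo + which.min(x[pre_lo:pre_hi]) - 1L else peaks[1]
  mids <- vapply(seq_len(length(peaks) - 1L), function(i) {
    lo <- peaks[i] + 1L
    hi <- peaks[i + 1L] - 1L
    if (hi < lo) stop("adjacent peaks with no interior samples")
    lo + which.min(x[lo:hi]) - 1L
  }, integer(1))
  c(pre, mids)
}

#' Compute per-beat morphological indices from landmarks
#'
#' A beat is (valley_i, peak_i, valley_(i+1)). Its indices are
#' BVA = amplitude(peak) - amplitude(onset valley), ST = time from onset
#' valley to peak, DT = time from peak to the next valley,
#' VVI = onset-to-onset interval (= ST + DT exactly), and
#' PPI = this peak to the next peak (undefined for the final beat). The
#' trailing peak without a closing valley is dropped.
#'
#' @param record A [ppg_record()] or numeric vector (then `fs` required).
#' @param landmarks A list with elements `peaks` and `valleys` (sample
#'   positions, as returned by [detect_peaks()] / [detect_valleys()]).
#' @param fs Sampling rate for bare vectors.
#' @return A beat table: `beat_idx`, `onset_s`, `peak_s`, `end_s`, `bva_mV`,
#'   `st_ms`, `dt_ms`, `ppi_ms` (`NA` for the final beat), `vvi_ms`.
#' @export
delineate_beats <- function(record, landmarks, fs = NULL) {
  is_rec <- inherits(record, "ppg_record")
  x <- if (is_rec) record$samples else as.numeric(record)
  if (is_rec) fs <- record$fs
  if (is.null(fs)) stop("fs required when record is a numeric vector")
  peaks <- as.integer(landmarks$peaks)
  valleys <- as.integer(landmarks$valleys)
  if (length(valleys) < 2L)
    stop("delineation error: need at least 2 valleys")
  # enforce alternating valley < peak < valley structure
  np <- min(length(peaks), length(valleys) - 1L)
  usable <- seq_len(np)
  ok <- valleys[usable] < peaks[usable] & peaks[usable] < valleys[usable + 1L]
  if (!all(ok))
    stop("delineation error: non-alternating landmarks at beat(s) ",
         paste(utils::head(which(!ok), 5), collapse = ", "))
  t_of <- function(i) (i - 1) / fs
  onset <- valleys[usable]
  nxt <- valleys[usable + 1L]
  pk <- peaks[usable]
  st <- (t_of(pk) - t_of(onset)) * 1000
  dt <- (t_of(nxt) - t_of(pk)) * 1000
  ppi <- c((diff(t_of(pk))) * 1000, NA_real_)
  data.frame(
    beat_idx = usable,
    onset_s = t_of(onset), peak_s = t_of(pk), end_s = t_of(nxt),
    bva_mV = x[pk] - x[onset],
    st_ms = st, dt_ms = dt, ppi_ms = ppi, vvi_ms = st + dt
  )
}

# refine a landmark to the local extremum of y within +/- win samples,
# constrained to (lo, hi) exclusive
refine_extremum <- function(y, pos, win, lo, hi, maximum = TRUE) {
  a <- max(lo + 1L, pos - win)
  b <- min(hi - 1L, pos + win)
  a <- as.integer(a); b <- as.integer(b); pos <- as.integer(pos)
  if (b < a) return(pos)
  seg <- y[a:b]
  a + (if (maximum) which.max(seg) else which.min(seg)) - 1L
}

#' Delineate a PPG record end to end
#'
#' Convenience pipeline. With `filter = "on"` (intended for noisy input):
#' band-pass the record to the measurement band, detect peaks on a smoother
#' detection copy (0.5--8 Hz band-pass, which suppresses baseline wander and
#' high-frequency noise so that candidate maxima are genuine systolic peaks),
#' refine each peak to the local maximum of the measurement signal, localize
#' each onset valley from the foot of the rising edge (see Details), and
#' compute beat indices. With `filter = "off"` the raw samples are used
#' throughout with plain argmin valleys -- appropriate for clean synthetic
#' input, where it gives sample-accurate timing.
#'
#' @details Under additive noise, argmin/argmax landmark timing is biased:
#' the diastolic tail approaches the onset level with vanishing slope and the
#' apex falls away only slowly on its diastolic side, so the extremum of
#' signal-plus-noise wanders across the locally flat region and lands
#' systematically on its flatter side. The noisy-path estimator therefore
#' anchors amplitudes at the inter-peak minimum (valley level) and local
#' maximum (apex level), but takes both landmark *times* from the quartile
#' crossings of the rising edge, where the signal-to-noise ratio is high:
#' for a raised-cosine upstroke the 25% and 75% amplitude crossings sit at
#' exactly one and two thirds of the upstroke, giving
#' `onset = 2 t25 - t75` and `apex = onset + 3 (t75 - t25)`. The constants
#' are specific to the raised-cosine pulse model this package synthesizes;
#' for real PPG morphologies the crossing fractions differ and would need
#' recalibration.
#'
#' @param record A [ppg_record()].
#' @param filter `"on"` (band-pass + two-signal detection; default for noisy
#'   data) or `"off"` (raw signal throughout).
#' @param low_hz,high_hz Measurement band when filtering (default 0.1--50 Hz).
#' @param min_distance_s,min_prominence_frac Passed to [detect_peaks()].
#' @param refine_ms Half-width, in ms, of the peak refinement window used
#'   when `filter = "on"` (default 80 ms; the apex region has high curvature, so a generous window adds no appreciable noise sensitivity).
#' @param artifact_gate If `TRUE` (default), beats whose timing falls outside
#'   plausible physiological ranges (ST 80--450 ms, DT 300--1200 ms) are
#'   rejected, and peak-to-peak intervals outside 300--1500 ms are masked.
#'   This removes the two-beat spans produced when a degenerate
#'   small-amplitude pulse escapes peak detection.
#' @return A beat table as from [delineate_beats()].
#' @export
delineate_record <- function(record, filter = c("on", "off"),
                             low_hz = 0.1, high_hz = 50,
                             min_distance_s = 0.33,
                             min_prominence_frac = 0.3,
                             refine_ms = 80,
                             artifact_gate = TRUE) {
  stopifnot(inherits(record, "ppg_record"))
  filter <- match.arg(filter)
  fs <- record$fs
  gate <- function(beats) {
    if (!artifact_gate) return(beats)
    ok <- beats$st_ms >= ST_RANGE_MS[1] & beats$st_ms <= ST_RANGE_MS[2] &
      beats$dt_ms >= DT_RANGE_MS[1] & beats$dt_ms <= DT_RANGE_MS[2]
    beats <- beats[ok, , drop = FALSE]
    bad_ppi <- !is.na(beats$ppi_ms) &
      (beats$ppi_ms < 300 | beats$ppi_ms > 1500)
    beats$ppi_ms[bad_ppi] <- NA_real_
    beats
  }
  if (filter == "off") {
    peaks <- detect_peaks(record, min_distance_s, min_prominence_frac)
    valleys <- detect_valleys(record, peaks)
    return(gate(delineate_beats(record,
                                list(peaks = peaks, valleys = valleys))))
  }
  if (length(refine_ms) == 1L) refine_ms <- rep(refine_ms, 2L)
  meas <- bandpass_filter(record, low_hz, high_hz)
  det <- bandpass_filter(record, 0.5, min(8, high_hz))
  peaks <- detect_peaks(det, min_distance_s, min_prominence_frac)
  if (length(peaks) < 2L) stop("too few peaks detected")
  y <- meas$samples
  n <- length(y)
  pw <- round(refine_ms[1] / 1000 * fs)
  # peaks refine cleanly on the measurement signal: the systolic apex is the
  # sharpest part of the pulse, so the local argmax is essentially unbiased
  peaks_r <- vapply(seq_along(peaks), function(i) {
    lo <- if (i == 1L) 1L else peaks[i - 1L]
    hi <- if (i == length(peaks)) n else peaks[i + 1L]
    refine_extremum(y, peaks[i], pw, lo, hi, maximum = TRUE)
  }, integer(1))
  # Both extrema sit in locally flat regions: the diastolic tail approaches
  # the onset with vanishing slope, and the apex falls away only slowly on
  # its diastolic side, so plain argmin/argmax landmark timing wanders under
  # noise and is biased toward the flatter side. The upstroke, in contrast,
  # is steep. Both landmark times are therefore taken from the quartile
  # crossings of the rising edge: for the raised-cosine upstroke
  # y(tau) = BVA/2 (1 - cos(pi tau / ST)), the 25% and 75% amplitude
  # crossings lie at exactly tau = ST/3 and 2 ST/3, so
  # onset = 2 t25 - t75 and apex = onset + 3 (t75 - t25).
  n_pk <- length(peaks_r)
  valleys_r <- integer(n_pk)
  apex_r <- integer(n_pk)
  for (i in seq_len(n_pk)) {
    lo <- if (i == 1L) 1L else peaks_r[i - 1L] + 1L
    seg <- y[lo:peaks_r[i]]
    level <- min(seg)
    bva <- y[peaks_r[i]] - level
    rise_from <- lo + which.min(seg) - 1L
    rseg <- y[rise_from:peaks_r[i]]
    i25 <- which(rseg >= level + 0.25 * bva)[1]
    i75 <- which(rseg >= level + 0.75 * bva)[1]
    if (is.na(i25) || is.na(i75) || i75 <= i25) {
      # degenerate rise: fall back to the raw landmarks
      valleys_r[i] <- rise_from
      apex_r[i] <- peaks_r[i]
      next
    }
    t25 <- (rise_from + i25 - 2L) / fs
    t75 <- (rise_from + i75 - 2L) / fs
    st_est <- 3 * (t75 - t25)
    t_v <- 2 * t25 - t75
    v <- as.integer(round(t_v * fs)) + 1L
    valleys_r[i] <- min(max(v, lo), peaks_r[i] - 1L)
    p <- as.integer(round((t_v + st_est) * fs)) + 1L
    apex_r[i] <- min(max(p, valleys_r[i] + 1L), n)
  }
  # keep the landmark sequence strictly alternating
  for (i in seq_len(max(n_pk - 1L, 0L)))
    if (apex_r[i] >= valleys_r[i + 1L])
      apex_r[i] <- valleys_r[i + 1L] - 1L
  gate(delineate_beats(meas, list(peaks = apex_r, valleys = valleys_r)))
}

#' Delineate every record of a cohort into one beat table
#'
#' @param cohort A `ppg_cohort` with rendered records.
#' @param use_truth If `TRUE`, bypass signal-level delineation and use the
#'   generator's beat truth tables (fast path for classifier-level work).
#' @param ... Passed to [delineate_record()].
#' @return A data.frame of beats with `subject_id` and `stage` prepended.
#' @export
delineate_cohort <- function(cohort, use_truth = FALSE, ...) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  man <- cohort$manifest
  out <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    key <- paste(man$subject_id[i], man$stage[i], sep = ".")
    beats <- if (use_truth) {
      cohort$truths[[key]]
    } else {
      if (is.null(cohort$records))
        stop("cohort has no rendered records; use use_truth = TRUE")
      delineate_record(cohort$records[[key]], ...)
    }
    if (nrow(beats))
      out[[i]] <- cbind(subject_id = man$subject_id[i], stage = man$stage[i],
                        beats, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
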
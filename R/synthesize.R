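#' @title Synthetic PPG generation
#' @description Beat-level draws, waveform rendering, and cohort assembly for
#'   the synthetic pulse cohorts used to exercise the pipeline.
#' @name synthesize
NULL

# physiological truncation bounds for drawn beat parameters (ms)
ST_RANGE_MS <- c(80, 450)
DT_RANGE_MS <- c(300, 1200)

rtruncnorm_vec <- function(n, mean, sd, lower, upper) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) {
    x <- rep(mean, n)
    if (any(x < lower | x > upper))
      stop("degenerate draw outside truncation bounds")
    return(x)
  }
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  tries <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
    tries <- tries + 1L
    if (tries > 1000L) {  # mean far outside the bounds
      x[bad] <- pmin(pmax(mean, lower), upper)
      break
    }
  }
  x
}

#' Draw a table of synthetic beats
#'
#' Draws per-beat systolic upstroke time (ST), diastolic time (DT) and blood
#' volume amplitude (BVA) independently from normal distributions truncated to
#' physiological ranges (ST in 80--450 ms, DT in 300--1200 ms, BVA > 0), and
#' lays the beats end to end: the beat period (valley-to-valley interval) is
#' ST + DT, and the peak-to-peak interval follows from consecutive onsets.
#' Either `n_beats` or `duration_s` (fill the interval with complete beats)
#' must be given.
#'
#' @param params One row of a stage parameter table (or a list) with elements
#'   `bva_mean`, `bva_sd`, `st_mean`, `st_sd`, `dt_mean`, `dt_sd`.
#' @param n_beats Number of beats to draw.
#' @param duration_s Alternatively, a duration to fill; beats are drawn until
#'   the next beat would end past `duration_s`.
#' @param seed Optional integer seed.
#' @return A `data.frame` (the beat truth table) with columns `beat_idx`,
#'   `onset_s`, `peak_s`, `end_s`, `bva_mV`, `st_ms`, `dt_ms`, `ppi_ms`
#'   (`NA` for the final beat), `vvi_ms`.
#' @export
synthesize_beats <- function(params, n_beats = NULL, duration_s = NULL,
                             seed = NULL) {
  if (is.null(n_beats) && is.null(duration_s))
    stop("give one of n_beats or duration_s")
  if (!is.null(seed)) set.seed(seed)
  p <- as.list(params)
  for (nm in c("bva_mean", "bva_sd", "st_mean", "st_sd", "dt_mean", "dt_sd"))
    if (is.null(p[[nm]])) stop("params lacks element ", nm)

  draw <- function(n) {
    data.frame(
      st_ms  = rtruncnorm_vec(n, p$st_mean, p$st_sd,
                              ST_RANGE_MS[1], ST_RANGE_MS[2]),
      dt_ms  = rtruncnorm_vec(n, p$dt_mean, p$dt_sd,
                              DT_RANGE_MS[1], DT_RANGE_MS[2]),
      bva_mV = rtruncnorm_vec(n, p$bva_mean, p$bva_sd, 1e-6, Inf)
    )
  }

  if (!is.null(n_beats)) {
    if (n_beats < 1) stop("n_beats must be >= 1")
    beats <- draw(as.integer(n_beats))
  } else {
    if (duration_s <= 0) stop("duration_s must be positive")
    period_s <- (p$st_mean + p$dt_mean) / 1000
    beats <- draw(max(4L, ceiling(duration_s / period_s * 1.25) + 8L))
    repeat {
      total <- sum(beats$st_ms + beats$dt_ms) / 1000
      if (total >= duration_s) break
      beats <- rbind(beats, draw(8L))
    }
    ends <- cumsum(beats$st_ms + beats$dt_ms) / 1000
    keep <- ends <= duration_s + 1e-9
    beats <- beats[keep, , drop = FALSE]
    if (nrow(beats) == 0)
      stop("duration_s too short to hold a single beat")
  }

  vvi <- beats$st_ms + beats$dt_ms
  onset_s <- c(0, cumsum(vvi[-length(vvi)])) / 1000
  peak_s  <- onset_s + beats$st_ms / 1000
  end_s   <- onset_s + vvi / 1000
  ppi <- c(diff(peak_s) * 1000, NA_real_)
  data.frame(
    beat_idx = seq_len(nrow(beats)),
    onset_s = onset_s, peak_s = peak_s, end_s = end_s,
    bva_mV = beats$bva_mV, st_ms = beats$st_ms, dt_ms = beats$dt_ms,
    ppi_ms = ppi, vvi_ms = vvi
  )
}

#' Render a beat truth table into a sampled PPG waveform
#'
#' Each beat is a raised-cosine upstroke of duration ST from the valley level
#' to valley + BVA, followed by a raised-cosine decay of duration DT back to
#' the valley level. Raised cosines have analytically known extrema, which is
#' what makes sample-accurate delineation checks possible.
#'
#' @param truth Beat table from [synthesize_beats()].
#' @param duration_s Record length in seconds; samples beyond the last
#'   complete beat are held at the valley level.
#' @param fs Sampling rate, samples/s (>= 128 so the upstroke is resolved).
#' @param noise_sd SD of additive white Gaussian noise, mV.
#' @param wander_amp Amplitude of 0.2 Hz sinusoidal baseline wander, mV.
#' @param wander_hz Baseline wander frequency, Hz.
#' @param seed Optional seed for the noise draw.
#' @return Numeric vector of `round(fs * duration_s)` amplitudes (mV).
#' @keywords internal
render_ppg_waveform <- function(truth, duration_s, fs,
                                noise_sd = 0, wander_amp = 0,
                                wander_hz = 0.2, seed = NULL) {
  n <- round(fs * duration_s)
  t <- (seq_len(n) - 1) / fs
  onset <- truth$onset_s
  b <- findInterval(t, onset)          # 0 before first beat (never: onset 0)
  amp <- numeric(n)
  inb <- b >= 1L & b <= nrow(truth)
  bi <- b[inb]
  rel <- t[inb] - onset[bi]
  st_s <- truth$st_ms[bi] / 1000
  dt_s <- truth$dt_ms[bi] / 1000
  bva <- truth$bva_mV[bi]
  rising <- rel < st_s
  val <- numeric(length(rel))
  val[rising] <- bva[rising] / 2 * (1 - cos(pi * rel[rising] / st_s[rising]))
  fall_rel <- rel[!rising] - st_s[!rising]
  # beyond the beat's end (trailing partial window) stay at the valley level
  fall_rel <- pmin(fall_rel, dt_s[!rising])
  val[!rising] <- bva[!rising] / 2 * (1 + cos(pi * fall_rel / dt_s[!rising]))
  amp[inb] <- val
  if (!is.null(seed)) set.seed(seed)
  if (wander_amp != 0) amp <- amp + wander_amp * sin(2 * pi * wander_hz * t)
  if (noise_sd > 0) amp <- amp + stats::rnorm(n, 0, noise_sd)
  amp
}

#' Construct a PPG record object
#'
#' @param samples Amplitude vector, mV.
#' @param fs Sampling rate, samples/s.
#' @param subject_id,stage Optional labels carried with the record.
#' @return An object of class `ppg_record`.
#' @export
ppg_record <- function(samples, fs, subject_id = NA_character_,
                       stage = NA_character_) {
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop("samples must be finite numeric")
  structure(
    list(samples = as.numeric(samples), fs = fs,
         duration_s = length(samples) / fs,
         subject_id = as.character(subject_id), stage = as.character(stage)),
    class = "ppg_record"
  )
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> %s/%s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$stage, length(x$samples), x$fs, x$duration_s))
  invisible(x)
}

#' Synthesize one PPG recording with beat-level ground truth
#'
#' Draws beats for the requested stage (from realized subject parameters or a
#' plain stage parameter row), renders the raised-cosine waveform, and
#' superimposes white noise and sinusoidal baseline wander.
#'
#' @param params A `subject_params` object (then `stage` selects the row) or a
#'   single-row stage parameter table / list.
#' @param stage Stage name, required when `params` is a `subject_params`.
#' @param duration_s Record duration, seconds (default 180, i.e. 3 min).
#' @param fs Sampling rate, samples/s; default 1024, must be >= 128.
#' @param noise_sd Additive white noise SD, mV (default 0.15).
#' @param wander_amp Baseline wander amplitude, mV (default 0.3 at 0.2 Hz).
#' @param seed Optional integer seed covering both beat draws and noise.
#' @return A list with elements `record` (a [ppg_record()]) and `truth`
#'   (the beat truth table from [synthesize_beats()]).
#' @examples
#' rec <- synthesize_record(default_stage_params()[1, ], duration_s = 20,
#'                          fs = 256, noise_sd = 0, wander_amp = 0, seed = 1)
#' nrow(rec$truth)
#' @export
synthesize_record <- function(params, stage = NULL, duration_s = 180,
                              fs = 1024, noise_sd = 0.15, wander_amp = 0.3,
                              seed = NULL) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (fs < 128)
    stop("fs must be >= 128 samples/s to resolve the systolic upstroke")
  subject_id <- NA_character_
  if (inherits(params, "subject_params")) {
    if (is.null(stage)) stop("stage must be given with subject_params")
    row <- params$stages[params$stages$stage == stage, , drop = FALSE]
    if (nrow(row) != 1) stop("unknown stage: ", stage)
    subject_id <- params$subject_id
    params <- row
  } else if (is.data.frame(params)) {
    if (nrow(params) != 1) stop("params must be a single row")
    if (is.null(stage) && !is.null(params$stage)) stage <- params$stage
  }
  if (!is.null(seed)) set.seed(seed)
  truth <- synthesize_beats(params, duration_s = duration_s)
  samples <- render_ppg_waveform(truth, duration_s, fs,
                                 noise_sd = noise_sd,
                                 wander_amp = wander_amp)
  rec <- ppg_record(samples, fs, subject_id = subject_id,
                    stage = if (is.null(stage)) NA_character_ else stage)
  list(record = rec, truth = truth)
}

#' Synthesize a multi-subject, multi-stage PPG cohort
#'
#' Generates one recording per subject per stage. Subject-level random effects
#' are shared across stages (see [sample_subject_params()]); every record and
#' every subject realization is seeded deterministically from the cohort seed,
#' so the whole cohort is a pure function of its configuration and seed.
#'
#' @param n_subjects Number of subjects (default 43).
#' @param stages Stage names to record (default all five).
#' @param duration_s,fs,noise_sd,wander_amp As in [synthesize_record()].
#' @param stage_params Population stage parameters.
#' @param between_sd_fraction Between-subject SD fraction, see
#'   [sample_subject_params()].
#' @param seed Cohort seed (integer).
#' @param render If `FALSE`, skip waveform rendering and return truth tables
#'   only (fast path when only beat-level quantities are needed).
#' @param subject_ids Optional explicit ids; must be unique.
#' @return An object of class `ppg_cohort`: list with `records` (named list of
#'   `ppg_record`, or `NULL` when `render = FALSE`), `truths` (named list of
#'   beat truth tables), `subjects` (list of `subject_params`), `manifest`
#'   (data.frame `subject_id`, `stage`, `fs`, `path`, `seed`), and the
#'   generating configuration.
#' @export
synthesize_cohort <- function(n_subjects = 43,
                              stages = ppg_stages(),
                              duration_s = 180, fs = 1024,
                              noise_sd = 0.15, wander_amp = 0.3,
                              stage_params = default_stage_params(),
                              between_sd_fraction = 0.6,
                              seed = 1, render = TRUE,
                              subject_ids = NULL) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (is.null(subject_ids))
    subject_ids <- sprintf("S%03d", seq_len(n_subjects))
  if (length(subject_ids) != n_subjects)
    stop("subject_ids length must equal n_subjects")
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  stages <- as.character(stages)
  if (!all(stages %in% stage_params$stage))
    stop("stages not present in stage_params")

  set.seed(seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  rec_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 n_subjects * length(stages)),
                      nrow = n_subjects)

  subjects <- vector("list", n_subjects)
  names(subjects) <- subject_ids
  records <- if (render) list() else NULL
  truths <- list()
  manifest <- vector("list", n_subjects * length(stages))
  k <- 0L
  for (i in seq_len(n_subjects)) {
    sp <- sample_subject_params(stage_params, between_sd_fraction,
                                subject_id = subject_ids[i],
                                seed = subj_seeds[i])
    subjects[[i]] <- sp
    for (j in seq_along(stages)) {
      k <- k + 1L
      key <- paste(subject_ids[i], stages[j], sep = ".")
      if (render) {
        out <- synthesize_record(sp, stage = stages[j],
                                 duration_s = duration_s, fs = fs,
                                 noise_sd = noise_sd,
                                 wander_amp = wander_amp,
                                 seed = rec_seeds[i, j])
        records[[key]] <- out$record
        truths[[key]] <- out$truth
      } else {
        set.seed(rec_seeds[i, j])
        row <- sp$stages[sp$stages$stage == stages[j], , drop = FALSE]
        truths[[key]] <- synthesize_beats(row, duration_s = duration_s)
      }
      manifest[[k]] <- data.frame(
        subject_id = subject_ids[i], stage = stages[j], fs = fs,
        path = NA_character_, seed = rec_seeds[i, j],
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(records = records, truths = truths, subjects = subjects,
         manifest = do.call(rbind, manifest),
         config = list(n_subjects = n_subjects, stages = stages,
                       duration_s = duration_s, fs = fs,
                       noise_sd = noise_sd, wander_amp = wander_amp,
                       between_sd_fraction = between_sd_fraction,
                       seed = seed)),
    class = "ppg_cohort"
  )
}

#' @export
print.ppg_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<ppg_cohort> %d subjects x %d stages, %g s @ %g Hz (seed %s)%s\n",
    cfg$n_subjects, length(cfg$stages), cfg$duration_s, cfg$fs,
    format(cfg$seed), if (is.null(x$records)) " [truth only]" else ""))
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Signals go to per-record CSVs (`time_s,amplitude_mV`), truth tables to
#' TSVs, and the manifest (with file paths filled in) to `manifest.tsv`.
#'
#' @param cohort A `ppg_cohort` with rendered records.
#' @param dir Output directory, created if needed.
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  if (is.null(cohort$records)) stop("cohort has no rendered records")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  for (i in seq_len(nrow(man))) {
    key <- paste(man$subject_id[i], man$stage[i], sep = ".")
    rec <- cohort$records[[key]]
    path <- file.path(dir, paste0(key, ".csv"))
    df <- data.frame(time_s = (seq_along(rec$samples) - 1) / rec$fs,
                     amplitude_mV = rec$samples)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    write_beats_tsv(cohort$truths[[key]],
                    file.path(dir, paste0(key, ".truth.tsv")))
    man$path[i] <- path
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(man)
}

#' Read a signal CSV written by [write_cohort()]
#' @param path CSV with header `time_s,amplitude_mV`.
#' @param fs Sampling rate; if `NULL`, inferred from the time column.
#' @param subject_id,stage Optional labels.
#' @return A [ppg_record()].
#' @export
read_ppg_csv <- function(path, fs = NULL, subject_id = NA_character_,
                         stage = NA_character_) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude_mV") %in% names(df)))
    stop("expected columns time_s, amplitude_mV in ", path)
  if (is.null(fs)) fs <- round(1 / stats::median(diff(df$time_s)))
  ppg_record(df$amplitude_mV, fs, subject_id = subject_id, stage = stage)
}

#' Write / read a beat table TSV
#' @param beats Beat table (truth or delineated).
#' @param path File path.
#' @export
write_beats_tsv <- function(beats, path) {
  utils::write.table(beats, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_beats_tsv
#' @export
read_beats_tsv <- function(path) {
  utils::read.delim(path)
}
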
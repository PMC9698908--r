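#' Reference per-stage pulse morphology parameters
#'
#' Population mean and standard deviation of the three primitive beat
#' morphology indices -- blood volume amplitude (BVA, mV), systolic upstroke
#' time (ST, ms) and diastolic time (DT, ms) -- for the five stages of an
#' emotion-recall protocol in hypertensive patients: a sitting baseline plus
#' neutral, anger, happiness and sadness recall. The inter-beat intervals are
#' emergent rather than primitive: a beat's valley-to-valley interval is
#' ST + DT by construction, and the peak-to-peak interval follows from
#' consecutive beats.
#'
#' These values parameterize [synthesize_record()] and [synthesize_cohort()].
#' Emotion activation shows up as lower pulse amplitude (peripheral
#' vasoconstriction) and longer systolic upstroke relative to baseline.
#'
#' @return A `data.frame` with one row per stage and columns `stage`,
#'   `bva_mean`, `bva_sd` (mV), `st_mean`, `st_sd`, `dt_mean`, `dt_sd` (ms).
#' @examples
#' default_stage_params()
#' @export
default_stage_params <- function() {
  params <- data.frame(
    stage    = c("baseline", "neutral", "anger", "happiness", "sadness"),
    bva_mean = c(11.82, 11.13, 8.23, 8.89, 8.39),
    bva_sd   = c(4.22, 4.25, 2.89, 3.13, 4.55),
    st_mean  = c(196.01, 205.59, 226.18, 218.83, 219.45),
    st_sd    = c(50.12, 57.01, 40.75, 41.22, 41.08),
    dt_mean  = c(650.84, 642.18, 627.04, 635.92, 618.28),
    dt_sd    = c(82.39, 84.08, 61.02, 79.94, 101.20),
    stringsAsFactors = FALSE
  )
  validate_stage_params(params)
  params
}

#' The five protocol stages, baseline first
#' @export
ppg_stages <- function() {
  c("baseline", "neutral", "anger", "happiness", "sadness")
}

validate_stage_params <- function(params) {
  stopifnot(is.data.frame(params))
  needed <- c("stage", "bva_mean", "bva_sd", "st_mean", "st_sd",
              "dt_mean", "dt_sd")
  missing <- setdiff(needed, names(params))
  if (length(missing))
    stop("stage parameter table lacks columns: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(params$stage))
    stop("duplicate stage names in stage parameter table")
  means <- as.matrix(params[, c("bva_mean", "st_mean", "dt_mean")])
  sds   <- as.matrix(params[, c("bva_sd", "st_sd", "dt_sd")])
  if (any(!is.finite(means)) || any(means <= 0))
    stop("all stage means must be finite and positive")
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("all stage SDs must be finite and nonnegative")
  # systole is faster than diastole in every stage we model
  if (any(params$st_mean >= params$dt_mean))
    stop("st_mean must be smaller than dt_mean for every stage")
  invisible(params)
}

#' Realize per-subject stage parameters with subject random effects
#'
#' Models stable individual differences: each subject gets one standard-normal
#' random effect per index (BVA, ST, DT), shared across stages, scaled by
#' `between_sd_fraction` times the stage's population SD and added to the
#' stage mean. The per-beat (within-subject) SD is shrunk to
#' `sqrt(1 - between_sd_fraction^2)` times the population SD so the marginal
#' beat distribution keeps the population spread. A shared random effect is
#' what makes baseline-subtracted (differential) features informative: the
#' subject offset cancels in the subtraction.
#'
#' @param stage_params Population table as from [default_stage_params()].
#' @param between_sd_fraction Fraction of each population SD allocated to the
#'   between-subject level, in `[0, 1]`. Default 0.6 (within fraction 0.8).
#' @param subject_id Identifier stored with the realization.
#' @param seed Integer seed making the realization reproducible.
#' @return An object of class `subject_params`: a list with `subject_id`,
#'   `between_sd_fraction`, `seed` and `stages`, a per-stage table of realized
#'   means and within-subject SDs (same columns as the population table).
#' @export
sample_subject_params <- function(stage_params = default_stage_params(),
                                  between_sd_fraction = 0.6,
                                  subject_id = "S01",
                                  seed = NULL) {
  validate_stage_params(stage_params)
  if (!is.numeric(between_sd_fraction) || length(between_sd_fraction) != 1 ||
      is.na(between_sd_fraction) ||
      between_sd_fraction < 0 || between_sd_fraction > 1)
    stop("between_sd_fraction must be a single number in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  f <- between_sd_fraction
  within_frac <- sqrt(1 - f^2)
  # one effect per index, shared across stages (stable trait)
  z <- stats::rnorm(3L)
  names(z) <- c("bva", "st", "dt")

  stages <- stage_params
  for (idx in c("bva", "st", "dt")) {
    mcol <- paste0(idx, "_mean")
    scol <- paste0(idx, "_sd")
    shifted <- stage_params[[mcol]] + z[[idx]] * f * stage_params[[scol]]
    # realized means must stay positive; reflect the rare overshoot
    stages[[mcol]] <- ifelse(shifted > 0, shifted, pmax(abs(shifted), 1e-6))
    stages[[scol]] <- within_frac * stage_params[[scol]]
  }
  # preserve the systolic < diastolic ordering invariant
  bad <- stages$st_mean >= stages$dt_mean
  if (any(bad)) {
    mid <- (stages$st_mean[bad] + stages$dt_mean[bad]) / 2
    stages$st_mean[bad] <- mid * 0.45
    stages$dt_mean[bad] <- mid * 1.55
  }
  validate_stage_params(stages)

  structure(
    list(subject_id = as.character(subject_id),
         between_sd_fraction = f,
         seed = seed,
         random_effects = z,
         stages = stages),
    class = "subject_params"
  )
}

#' @export
print.subject_params <- function(x, ...) {
  cat("<subject_params> ", x$subject_id,
      "  (between-subject SD fraction ", x$between_sd_fraction, ")\n", sep = "")
  print(x$stages, row.names = FALSE)
  invisible(x)
}
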
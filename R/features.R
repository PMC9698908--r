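#' @title Segment featurization
#' @description Conversion of delineated beats into per-segment feature
#'   vectors (mean and STD of the five morphological indices over each 30 s
#'   segment), differential features relative to the subject's baseline, and
#'   assembled classification matrices.
#' @name featurization
NULL

FEATURE_INDICES <- c("bva", "st", "dt", "ppi", "vvi")

#' Names of the 10 per-segment waveform features
#' @param differential If `TRUE`, return the names of the differential
#'   (baseline-subtracted) block, prefixed `d_`.
#' @return Character vector of length 10.
#' @export
waveform_feature_names <- function(differential = FALSE) {
  nm <- as.vector(t(outer(FEATURE_INDICES, c("mean", "std"), paste,
                          sep = "_")))
  if (differential) paste0("d_", nm) else nm
}

index_column <- function(idx) {
  c(bva = "bva_mV", st = "st_ms", dt = "dt_ms",
    ppi = "ppi_ms", vvi = "vvi_ms")[[idx]]
}

pop_sd <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

#' Assign beats to non-overlapping time segments
#'
#' Beats belong to the half-open window `[k*window_s, (k+1)*window_s)` that
#' contains their onset valley. A 180 s record with 30 s windows yields six
#' segments. A trailing partial window (when `duration_s` is not a multiple
#' of `window_s`) is dropped with a warning.
#'
#' @param beats A beat table (truth or delineated).
#' @param duration_s Record duration, seconds.
#' @param window_s Segment length, seconds (default 30).
#' @return The beat table with a `segment_idx` column (1-based); beats past
#'   the last full window are removed.
#' @export
segment_beats <- function(beats, duration_s, window_s = 30) {
  if (window_s <= 0) stop("window_s must be positive")
  n_seg <- floor(duration_s / window_s + 1e-9)
  if (n_seg < 1) stop("duration shorter than one window")
  if (abs(duration_s - n_seg * window_s) > 1e-9)
    warning("duration_s is not a multiple of window_s; ",
            "trailing partial window dropped")
  seg <- floor(beats$onset_s / window_s) + 1L
  keep <- seg >= 1L & seg <= n_seg
  out <- beats[keep, , drop = FALSE]
  out$segment_idx <- as.integer(seg[keep])
  out
}

#' Representative features of one beat group
#'
#' The arithmetic mean and the population standard deviation (divisor n) of
#' each of the five indices across the group's beats: 10 features. The final
#' beat's undefined peak-to-peak interval is excluded pairwise.
#'
#' @param beats Beats of a single segment (>= 3 beats required).
#' @return Named numeric vector of length 10
#'   (`bva_mean, bva_std, ..., vvi_std`).
#' @export
segment_features <- function(beats) {
  if (nrow(beats) < 3L)
    stop("invalid segment: fewer than 3 beats")
  out <- numeric(0)
  for (idx in FEATURE_INDICES) {
    v <- beats[[index_column(idx)]]
    out[paste0(idx, "_mean")] <- mean(v, na.rm = TRUE)
    out[paste0(idx, "_std")] <- pop_sd(v)
  }
  out
}

#' Per-segment feature table for a cohort's beats
#'
#' Segments every (subject, stage) record and computes the 10 waveform
#' features per segment. Segments with fewer than 3 beats are excluded.
#'
#' @param beats Cohort beat table from [delineate_cohort()] (must carry
#'   `subject_id` and `stage` columns).
#' @param duration_s,window_s Segmentation parameters (defaults 180 s / 30 s).
#' @return Data.frame with `subject_id`, `stage`, `segment_idx` and the 10
#'   feature columns.
#' @export
featurize_cohort <- function(beats, duration_s = 180, window_s = 30) {
  stopifnot(all(c("subject_id", "stage") %in% names(beats)))
  grp <- interaction(beats$subject_id, beats$stage, drop = TRUE)
  pieces <- lapply(split(beats, grp), function(b) {
    sb <- segment_beats(b, duration_s, window_s)
    segs <- split(sb, sb$segment_idx)
    rows <- lapply(segs, function(s) {
      if (nrow(s) < 3L) return(NULL)  # invalid segment, excluded
      cbind(data.frame(subject_id = s$subject_id[1], stage = s$stage[1],
                       segment_idx = s$segment_idx[1],
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(segment_features(s))))
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$subject_id, out$stage, out$segment_idx), , drop = FALSE]
}

#' A subject's baseline feature reference
#'
#' The per-feature mean across the subject's valid baseline segments; the
#' anchor from which differential features are measured.
#'
#' @param features Feature rows (as from [featurize_cohort()]) of one
#'   subject's baseline stage.
#' @return Named numeric vector of length 10.
#' @export
baseline_reference <- function(features) {
  cols <- waveform_feature_names()
  if (!nrow(features)) stop("no valid baseline segments for subject")
  colMeans(as.matrix(features[, cols, drop = FALSE]))
}

#' Differential features: activated state minus baseline
#'
#' @param state Named feature vector (or single feature row) of an activated
#'   segment.
#' @param reference Baseline reference vector from [baseline_reference()].
#' @return Named numeric vector, `d_`-prefixed, elementwise
#'   `state - reference`.
#' @export
differential_features <- function(state, reference) {
  if (is.data.frame(state)) {
    state <- unlist(state[1, waveform_feature_names(), drop = FALSE])
  }
  if (!all(names(reference) %in% names(state)))
    stop("feature name mismatch between state and reference")
  d <- state[names(reference)] - reference
  names(d) <- paste0("d_", names(reference))
  d
}

TASKS_BASELINE <- paste0("baseline_vs_",
                         c("neutral", "anger", "happiness", "sadness"))
TASKS_MULTI <- c("2C", "3C", "4C")

#' The classification tasks reproduced by the pipeline
#' @return Character vector of task names: four binary baseline-vs-state
#'   tasks plus the 2C/3C/4C emotion categorizations.
#' @export
ppg_tasks <- function() c(TASKS_BASELINE, TASKS_MULTI)

task_label <- function(task, stage) {
  switch(task,
    "2C" = ifelse(stage %in% c("anger", "sadness"), "negative", "positive"),
    "3C" = ifelse(stage %in% c("anger", "sadness"), "negative",
                  ifelse(stage == "neutral", "neutral", "positive")),
    "4C" = stage,
    # baseline-vs-state binary tasks
    ifelse(stage == "baseline", "baseline", "state")
  )
}

task_stages <- function(task) {
  if (task %in% TASKS_MULTI)
    c("neutral", "anger", "happiness", "sadness")
  else if (task %in% TASKS_BASELINE)
    c("baseline", sub("baseline_vs_", "", task))
  else stop("unknown task: ", task)
}

#' Assemble a labelled classification matrix
#'
#' Restricts the cohort's segment features to the stages of one task and
#' attaches labels, the segment-fold column, and the requested feature block:
#' the 10 waveform features, the 10 differential features (each segment minus
#' the subject's baseline reference; baseline rows, present only in the
#' binary tasks, carry their own difference from the reference), or both
#' concatenated (20 features, waveform block first).
#'
#' Task label schemes: the four `baseline_vs_*` tasks are binary
#' baseline/state; `2C` is negative (anger, sadness) vs positive (neutral,
#' happiness); `3C` splits neutral out of the positive class (positive =
#' happiness); `4C` keeps the four recall stages as separate classes.
#' Baseline rows do not participate in the 2C/3C/4C tasks.
#'
#' @param features Segment feature table from [featurize_cohort()].
#' @param feature_set One of `"waveform10"`, `"differential10"`,
#'   `"combined20"`.
#' @param task One of [ppg_tasks()].
#' @param diff_pairing How an activated segment is paired with the baseline
#'   for the differential block: `"mean"` (default; subtract the subject's
#'   mean over all baseline segments, the lowest-variance realization) or
#'   `"matched"` (subtract the baseline segment with the same segment
#'   index).
#' @return A data.frame with key columns (`subject_id`, `stage`,
#'   `segment_idx`, `fold`, `label`) followed by the feature columns; the
#'   feature column names are stored in `attr(, "feature_cols")`.
#' @export
assemble_matrix <- function(features,
                            feature_set = c("waveform10", "differential10",
                                            "combined20"),
                            task = "4C",
                            diff_pairing = c("mean", "matched")) {
  feature_set <- match.arg(feature_set)
  diff_pairing <- match.arg(diff_pairing)
  if (!task %in% ppg_tasks()) stop("unknown task: ", task)
  wcols <- waveform_feature_names()

  need_diff <- feature_set %in% c("differential10", "combined20")
  if (need_diff) {
    base <- features[features$stage == "baseline", , drop = FALSE]
    refs <- lapply(split(base, base$subject_id), baseline_reference)
    with_ref <- names(refs)
    dropped <- setdiff(unique(features$subject_id), with_ref)
    if (length(dropped))
      warning("subjects without baseline segments excluded: ",
              paste(dropped, collapse = ", "))
    features <- features[features$subject_id %in% with_ref, , drop = FALSE]
    ref_for <- function(i) {
      if (diff_pairing == "matched") {
        hit <- base$subject_id == features$subject_id[i] &
          base$segment_idx == features$segment_idx[i]
        if (any(hit))
          return(unlist(base[which(hit)[1], wcols]))
        # fall back to the mean reference when the matched segment is absent
      }
      refs[[features$subject_id[i]]]
    }
    dmat <- t(vapply(seq_len(nrow(features)), function(i) {
      r <- ref_for(i)
      names(r) <- wcols
      differential_features(unlist(features[i, wcols]), r)
    }, numeric(length(wcols))))
    features <- cbind(features, as.data.frame(dmat))
  }

  rows <- features[features$stage %in% task_stages(task), , drop = FALSE]
  fcols <- switch(feature_set,
                  waveform10 = wcols,
                  differential10 = waveform_feature_names(TRUE),
                  combined20 = c(wcols, waveform_feature_names(TRUE)))
  out <- cbind(
    data.frame(subject_id = rows$subject_id, stage = rows$stage,
               segment_idx = rows$segment_idx,
               fold = rows$segment_idx,
               label = task_label(task, rows$stage),
               stringsAsFactors = FALSE),
    rows[, fcols, drop = FALSE]
  )
  rownames(out) <- NULL
  if (anyNA(out[, fcols])) stop("assembled matrix contains missing values")
  attr(out, "feature_cols") <- fcols
  attr(out, "task") <- task
  attr(out, "feature_set") <- feature_set
  out
}

#' Feature column names of an assembled matrix
#' @param m Matrix from [assemble_matrix()].
#' @export
feature_columns <- function(m) attr(m, "feature_cols")

#' Fit / apply leakage-free z-score normalization
#'
#' `zscore_fit` estimates per-column mean and standard deviation from
#' training rows only; `zscore_apply` standardizes any rows with those frozen
#' statistics. A constant training column (SD 0) maps to 0 with a warning.
#' Keeping fit and apply separate is what guarantees that no test-fold
#' statistic ever enters the normalization.
#'
#' @param x Numeric matrix or data.frame of training feature rows (>= 2
#'   rows).
#' @return `zscore_fit`: an object of class `zscore_model` with `center`,
#'   `scale` and `constant` flags.
#' @export
zscore_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 training rows")
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  constant <- scale == 0 | !is.finite(scale)
  structure(list(center = center, scale = scale, constant = constant),
            class = "zscore_model")
}

#' @rdname zscore_fit
#' @param model A fitted `zscore_model`.
#' @param newx Rows to standardize (same columns as the training rows).
#' @return `zscore_apply`: the standardized numeric matrix.
#' @export
zscore_apply <- function(model, newx) {
  stopifnot(inherits(model, "zscore_model"))
  newx <- as.matrix(newx)
  if (ncol(newx) != length(model$center))
    stop("column count mismatch with fitted model")
  out <- sweep(newx, 2, model$center, "-")
  if (any(model$constant)) {
    warning("constant training column(s) mapped to 0: ",
            paste(names(model$center)[model$constant], collapse = ", "))
    out[, model$constant] <- 0
  }
  sc <- ifelse(model$constant, 1, model$scale)
  sweep(out, 2, sc, "/")
}
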
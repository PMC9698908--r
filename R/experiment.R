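#' @title Experiment runner
#' @description Executes the full evaluation grid on a synthetic cohort --
#'   tasks x feature sets x validation schemes x feature selection -- and
#'   emits the three report tables: baseline-vs-state accuracies, emotion
#'   categorization accuracies with and without selection, and the
#'   selected-feature incidence grid.
#' @name experiment
NULL

#' Experiment configuration
#'
#' @param svm An [svm_config()].
#' @param ga A [ga_config()] for selection on the 20-feature combined block.
#' @param feature_sets Feature sets evaluated in the categorization tables.
#' @param tasks Multi-class tasks to run (default 2C/3C/4C).
#' @param baseline_feature_set Feature set for the four baseline-vs-state
#'   tasks (default the 10 waveform features).
#' @param selection `TRUE` to run wrapper selection (full search for the
#'   10-feature blocks, the genetic algorithm for the 20-feature block).
#' @param seed Master seed; per-cell seeds are derived from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(svm = svm_config(),
                              ga = ga_config(),
                              feature_sets = c("waveform10", "differential10",
                                               "combined20"),
                              tasks = c("2C", "3C", "4C"),
                              baseline_feature_set = "waveform10",
                              selection = TRUE,
                              seed = 1) {
  structure(list(svm = svm, ga = ga, feature_sets = feature_sets,
                 tasks = tasks,
                 baseline_feature_set = baseline_feature_set,
                 selection = selection, seed = seed),
            class = "experiment_config")
}

#' Run the full classification experiment on a cohort feature table
#'
#' @param features Segment feature table from [featurize_cohort()].
#' @param config An [experiment_config()].
#' @return An object of class `experiment_report`: list with
#'   `baseline_table` (validation x four baseline-vs-state tasks),
#'   `categorization_table` (selection x feature set x task accuracies under
#'   six-fold CV), `incidence` (selected-feature grid for the combined block,
#'   tasks as columns), `selections` (per-cell selection details) and
#'   `config`.
#' @export
run_experiment <- function(features, config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, 64L)
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    cell_seeds[seed_i]
  }

  # --- baseline-vs-state table (both validation schemes, no selection)
  base_rows <- lapply(c("resubstitution", "sixfold"), function(scheme) {
    accs <- vapply(TASKS_BASELINE, function(task) {
      m <- assemble_matrix(features, config$baseline_feature_set, task)
      matrix_accuracy(m, config$svm, scheme)
    }, numeric(1))
    cbind(data.frame(validation = scheme, stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(
            accs, sub("baseline_vs_", "", TASKS_BASELINE)))))
  })
  baseline_table <- do.call(rbind, base_rows)

  # --- categorization table (six-fold CV, with and without selection)
  selections <- list()
  cat_rows <- list()
  sel_modes <- if (isTRUE(config$selection)) c("none", "selected") else "none"
  for (mode in sel_modes) {
    for (fset in config$feature_sets) {
      accs <- vapply(config$tasks, function(task) {
        m <- assemble_matrix(features, fset, task)
        if (mode == "none")
          return(matrix_accuracy(m, config$svm, "sixfold"))
        ev <- subset_cv_evaluator(m, config$svm, "sixfold")
        res <- if (fset == "combined20") {
          cfg <- config$ga
          cfg$seed <- next_seed()
          ga_select(ev, config = cfg)
        } else {
          full_search(ev)
        }
        selections[[paste(mode, fset, task, sep = ".")]] <<- list(
          feature_set = fset, task = task,
          features = feature_columns(m)[res$subset],
          bits = res$bits, fitness = res$fitness)
        res$fitness
      }, numeric(1))
      cat_rows[[paste(mode, fset)]] <- cbind(
        data.frame(selection = mode, feature_set = fset,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(stats::setNames(accs, config$tasks)),
                      check.names = FALSE))
    }
  }
  categorization_table <- NULL
  if (length(cat_rows)) {
    categorization_table <- do.call(rbind, cat_rows)
    rownames(categorization_table) <- NULL
  }

  # --- incidence grid of selected combined-block features per task
  incidence <- NULL
  sel_keys <- grep("^selected\\.combined20\\.", names(selections),
                   value = TRUE)
  if (length(sel_keys)) {
    all_feats <- c(waveform_feature_names(), waveform_feature_names(TRUE))
    incidence <- data.frame(feature = all_feats, stringsAsFactors = FALSE)
    for (key in sel_keys) {
      task <- sub("^selected\\.combined20\\.", "", key)
      incidence[[task]] <-
        ifelse(all_feats %in% selections[[key]]$features, "X", "")
    }
  }

  structure(list(baseline_table = baseline_table,
                 categorization_table = categorization_table,
                 incidence = incidence,
                 selections = selections,
                 config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("== Baseline vs activated stage (accuracy) ==\n")
  print(x$baseline_table, row.names = FALSE, digits = 4)
  if (!is.null(x$categorization_table)) {
    cat("\n== Emotion categorization, six-fold CV (accuracy) ==\n")
    print(x$categorization_table, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$incidence)) {
    cat("\n== Selected combined-block features ==\n")
    print(x$incidence, row.names = FALSE)
  }
  invisible(x)
}

#' Write an experiment report to TSV files
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$baseline_table, "baseline_vs_state.tsv")
  if (!is.null(report$categorization_table))
    wr(report$categorization_table, "categorization.tsv")
  if (!is.null(report$incidence)) wr(report$incidence, "incidence.tsv")
  invisible(paths)
}
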
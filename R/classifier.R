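#' @title One-against-all RBF SVM and validation schemes
#' @description Binary machines are libsvm C-classification SVMs with a
#'   radial basis kernel (via e1071); the one-against-all assembly,
#'   decision-value tie-break, segment-wise fold construction and the two
#'   validation schemes (resubstitution and six-fold cross-validation with
#'   leakage-free normalization) are implemented here.
#' @name classifier
NULL

#' Classifier configuration
#'
#' @param C Soft-margin cost parameter, > 0 (default 10).
#' @param gamma RBF kernel width, > 0, or `"auto"` =
#'   `1 / (n_features * pooled feature variance)` computed on the training
#'   rows (for z-scored features this is about `1/n_features`).
#' @param seed Optional seed (the SVM fit itself is deterministic; the seed
#'   is recorded for provenance).
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(C = 10, gamma = "auto", seed = NULL) {
  if (!is.numeric(C) || C <= 0) stop("C must be positive")
  if (!(identical(gamma, "auto") || (is.numeric(gamma) && gamma > 0)))
    stop("gamma must be positive or \"auto\"")
  structure(list(C = C, gamma = gamma, kernel = "radial",
                 multiclass = "one-against-all", seed = seed),
            class = "svm_config")
}

resolve_gamma <- function(config, x) {
  if (identical(config$gamma, "auto")) {
    pooled <- mean(apply(x, 2, stats::var))
    if (!is.finite(pooled) || pooled <= 0) pooled <- 1
    1 / (ncol(x) * pooled)
  } else config$gamma
}

fit_binary_svm <- function(x, y01, config, gamma) {
  # y01: factor with positive class as first level
  fit <- e1071::svm(x, y01, type = "C-classification", kernel = "radial",
                    cost = config$C, gamma = gamma, scale = FALSE)
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")[, 1]
  # libsvm's decision sign follows its internal label order; normalize so
  # positive decision values mean the positive class
  flip <- mean(dv[y01 == levels(y01)[1]]) < mean(dv[y01 == levels(y01)[2]])
  list(fit = fit, flip = flip)
}

#' Train a one-against-all RBF SVM
#'
#' For K > 2 classes, trains K binary machines (class k vs the rest);
#' prediction is the argmax of the K decision values, ties resolved in favor
#' of the lowest class index (factor level order). For K = 2 a single binary
#' machine is trained and its decision sign used directly.
#'
#' @param x Numeric feature matrix (already normalized).
#' @param y Class labels (coerced to factor; >= 2 classes required).
#' @param config An [svm_config()].
#' @return An object of class `ova_svm`.
#' @export
train_classifier <- function(x, y, config = svm_config()) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop("training set contains a single class")
  if (any(table(y) == 0)) y <- droplevels(y)
  gamma <- resolve_gamma(config, x)
  classes <- levels(y)
  machines <- lapply(classes, function(k) {
    yk <- factor(ifelse(y == k, "pos", "neg"), levels = c("pos", "neg"))
    fit_binary_svm(x, yk, config, gamma)
  })
  names(machines) <- classes
  structure(list(machines = machines, classes = classes,
                 gamma = gamma, config = config, n_features = ncol(x)),
            class = "ova_svm")
}

#' @export
predict.ova_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("feature count mismatch")
  dec <- vapply(object$machines, function(m) {
    dv <- attr(stats::predict(m$fit, newdata, decision.values = TRUE),
               "decision.values")[, 1]
    if (m$flip) -dv else dv
  }, numeric(nrow(newdata)))
  dec <- matrix(dec, nrow = nrow(newdata),
                dimnames = list(NULL, object$classes))
  # argmax with ties to the lowest class index
  idx <- apply(dec, 1, which.max)
  factor(object$classes[idx], levels = object$classes)
}

#' Segment-index fold assignment
#'
#' Folds are the segment indices themselves: fold k holds the k-th 30 s
#' segment of every (subject, stage) recording, so each recording contributes
#' exactly one segment per fold and the assignment is deterministic.
#' (Subject, stage) groups that do not have the full complement of segments
#' are dropped with a warning.
#'
#' @param matrix_df Assembled matrix from [assemble_matrix()] (needs
#'   `subject_id`, `stage`, `segment_idx` / `fold` columns).
#' @param n_folds Number of folds (default 6, the segments per 3-min record).
#' @return Integer vector of fold ids (1..n_folds) aligned with the rows,
#'   `NA` for dropped rows.
#' @export
make_folds <- function(matrix_df, n_folds = 6) {
  seg <- matrix_df$segment_idx
  grp <- paste(matrix_df$subject_id, matrix_df$stage, sep = ".")
  counts <- tapply(seg, grp, function(s)
    length(s) == n_folds && setequal(s, seq_len(n_folds)))
  bad <- names(counts)[!counts]
  folds <- as.integer(seg)
  if (length(bad)) {
    warning("dropping (subject, stage) groups without all ", n_folds,
            " segments: ", paste(utils::head(bad, 5), collapse = ", "),
            if (length(bad) > 5) " ..." else "")
    folds[grp %in% bad] <- NA_integer_
  }
  folds
}

#' Resubstitution (all-train-all-test) accuracy
#'
#' Normalization statistics and the classifier are both fitted on the entire
#' dataset, and the same rows are predicted: a self-consistency ceiling, not
#' a generalization estimate.
#'
#' @param x Raw (un-normalized) feature matrix.
#' @param y Labels.
#' @param config An [svm_config()].
#' @return Fraction of rows predicted correctly.
#' @export
resubstitution_accuracy <- function(x, y, config = svm_config()) {
  x <- as.matrix(x)
  y <- factor(y)
  zm <- zscore_fit(x)
  xs <- zscore_apply(zm, x)
  model <- train_classifier(xs, y, config)
  mean(predict(model, xs) == y)
}

#' Six-fold (segment-wise) cross-validated accuracy
#'
#' For each fold: z-score statistics are fitted on the five training folds
#' only, the classifier is trained on those rows, and the held-out fold is
#' predicted after being standardized with the training statistics. The
#' reported accuracy is the unweighted mean of the per-fold accuracies.
#'
#' @param x Raw feature matrix.
#' @param y Labels.
#' @param folds Fold ids from [make_folds()]; `NA` rows are excluded.
#' @param config An [svm_config()].
#' @return List with `mean` accuracy and `per_fold` vector.
#' @export
kfold_cv_accuracy <- function(x, y, folds, config = svm_config()) {
  x <- as.matrix(x)
  y <- factor(y)
  keep <- !is.na(folds)
  x <- x[keep, , drop = FALSE]; y <- y[keep]; folds <- folds[keep]
  ids <- sort(unique(folds))
  acc <- vapply(ids, function(k) {
    tr <- folds != k
    if (nlevels(droplevels(y[tr])) < nlevels(droplevels(y)))
      stop("fold ", k, ": a class is absent from the training folds")
    zm <- zscore_fit(x[tr, , drop = FALSE])
    model <- train_classifier(zscore_apply(zm, x[tr, , drop = FALSE]),
                              droplevels(y[tr]), config)
    pred <- predict(model, zscore_apply(zm, x[!tr, , drop = FALSE]))
    mean(as.character(pred) == as.character(y[!tr]))
  }, numeric(1))
  list(mean = mean(acc), per_fold = stats::setNames(acc, ids))
}

#' Accuracy of an assembled matrix under a validation scheme
#'
#' Thin wrapper tying [assemble_matrix()] output to the two validation
#' schemes, optionally restricted to a feature subset.
#'
#' @param matrix_df Assembled matrix.
#' @param config An [svm_config()].
#' @param scheme `"resubstitution"` or `"sixfold"`.
#' @param subset Optional integer indices into the matrix's feature columns.
#' @return Accuracy (scalar).
#' @export
matrix_accuracy <- function(matrix_df, config = svm_config(),
                            scheme = c("sixfold", "resubstitution"),
                            subset = NULL) {
  scheme <- match.arg(scheme)
  fcols <- feature_columns(matrix_df)
  if (!is.null(subset)) fcols <- fcols[subset]
  x <- as.matrix(matrix_df[, fcols, drop = FALSE])
  y <- factor(matrix_df$label)
  if (scheme == "resubstitution")
    resubstitution_accuracy(x, y, config)
  else
    kfold_cv_accuracy(x, y, make_folds(matrix_df), config)$mean
}
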
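#' Specify a classifier family
#'
#' Two families are supported: linear discriminant analysis (`"lda"`,
#' delegated to [MASS::lda()]) and a linear-kernel support vector machine
#' (`"svm_linear"`, in-package hinge-loss SVM with cost 1).  Following the
#' assessment protocol, no hyperparameters are tuned; the library defaults
#' are recorded in the spec for reproducibility.
#'
#' @param family `"lda"` or `"svm_linear"`.
#' @param hyperparameters named list; empty by default and normally left so.
#' @return a `model_spec` list.
#' @export
model_spec <- function(family = c("lda", "svm_linear"),
                       hyperparameters = list()) {
  family <- match.arg(family)
  defaults <- switch(family,
                     lda = list(prior = "class proportions", method = "mle"),
                     svm_linear = list(cost = 1, tol = 0.01,
                                       max_epochs = 1000L))
  structure(list(family = family,
                 hyperparameters = hyperparameters,
                 defaults = defaults),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (defaults: %s)\n", x$family,
              paste(names(x$defaults), unlist(x$defaults), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

.check_parsimony <- function(dataset) {
  n <- n_profiles(dataset)
  if (n > 2L) {
    guard <- parsimony_guard(n, 2L)
    if (n_bands(dataset) > guard$max_bands) {
      warning(sprintf(paste0("parsimony guard: %d bands exceed the maximum ",
                             "%d = floor((%d objects - 2 classes)/3); ",
                             "risk of over-fitting"),
                      n_bands(dataset), guard$max_bands, n), call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Train a classifier on a full dataset
#'
#' Fits the requested family on all profiles.  Emits a parsimony-guard
#' warning when the number of bands exceeds `floor((objects - classes)/3)`;
#' an LDA failure from a singular within-class covariance is re-thrown with
#' the same hint.
#'
#' @param dataset a [spectral_dataset()] with both classes non-empty.
#' @param model a [model_spec()].
#' @return an opaque fitted handle of class `spec_classifier`, supporting
#'   [predict()] on any dataset with the same band grid.
#' @export
train_full <- function(dataset, model) {
  stopifnot(inherits(dataset, "spectral_dataset"),
            inherits(model, "model_spec"))
  cb <- class_counts(dataset)
  if (cb$n_class0 == 0L || cb$n_class1 == 0L) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  .check_parsimony(dataset)
  y <- dataset$meta$label
  fit <- if (model$family == "lda") {
    tryCatch(
      MASS::lda(dataset$reflectance, grouping = factor(y, levels = 0:1)),
      error = function(e) {
        stop(sprintf(paste0("LDA fit failed (%s); with %d objects the ",
                            "parsimony rule caps bands at %d -- consider ",
                            "reducing bands or adding objects"),
                     conditionMessage(e), n_profiles(dataset),
                     parsimony_guard(n_profiles(dataset), 2L)$max_bands),
             call. = FALSE)
      })
  } else {
    fit_linear_svm(dataset$reflectance, y)
  }
  structure(list(family = model$family, fit = fit, model = model,
                 wavelengths = dataset$wavelengths,
                 n_train = n_profiles(dataset)),
            class = "spec_classifier")
}

#' Predict germination labels
#'
#' @param object a fitted `spec_classifier` from [train_full()].
#' @param dataset a [spectral_dataset()] on the same band grid (or a bare
#'   reflectance matrix with matching column count).
#' @param ... unused.
#' @return integer vector of predicted labels in `{0, 1}`.
#' @export
predict.spec_classifier <- function(object, dataset, ...) {
  x <- if (inherits(dataset, "spectral_dataset")) {
    if (!isTRUE(all.equal(dataset$wavelengths, object$wavelengths))) {
      stop("band grid of the data does not match the trained model",
           call. = FALSE)
    }
    dataset$reflectance
  } else {
    x <- as.matrix(dataset)
    if (ncol(x) != length(object$wavelengths)) {
      stop(sprintf("model expects %d bands, data has %d",
                   length(object$wavelengths), ncol(x)), call. = FALSE)
    }
    x
  }
  if (object$family == "lda") {
    as.integer(as.character(predict(object$fit, x)$class))
  } else {
    as.integer(decision_linear_svm(object$fit, x) > 0)
  }
}

#' Stratified k-fold cross-validated accuracy
#'
#' Objects are partitioned into `k` stratified folds (class proportions
#' preserved); for each fold the model is trained on the other `k - 1` folds
#' and scored on the held-out fold.  The headline `accuracy_pct` is pooled
#' (micro-averaged) over all held-out predictions; per-fold accuracies are
#' retained.  Deterministic given `(dataset, model, k, rng_seed)`.
#'
#' @param dataset a [spectral_dataset()]; each class needs `>= k` members.
#' @param model a [model_spec()].
#' @param k fold count (default 10).
#' @param rng_seed integer seed for the fold assignment.
#' @return a `cv_result` list: `accuracy_pct`, `per_fold_accuracy`,
#'   `fold_sizes`, `k`, `model_spec`, `rng_seed`.
#' @export
cross_validated_accuracy <- function(dataset, model, k = 10L,
                                     rng_seed = 1L) {
  stopifnot(inherits(dataset, "spectral_dataset"),
            inherits(model, "model_spec"), k >= 2L)
  y <- dataset$meta$label
  cb <- class_counts(dataset)
  if (cb$n_class0 == 0L || cb$n_class1 == 0L) {
    stop("degenerate dataset: one class absent", call. = FALSE)
  }
  if (min(cb$n_class0, cb$n_class1) < k) {
    stop(sprintf("smallest class has %d members, fewer than k = %d folds",
                 min(cb$n_class0, cb$n_class1), k), call. = FALSE)
  }
  fold <- integer(length(y))
  withr::with_seed(rng_seed, {
    for (cls in 0:1) {
      idx <- which(y == cls)
      fold[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(k), length(idx))
    }
  })
  correct <- logical(length(y))
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    hold <- fold == f
    fit <- train_full(subset_profiles(dataset, which(!hold)), model)
    pred <- predict(fit, dataset$reflectance[hold, , drop = FALSE])
    correct[hold] <- pred == y[hold]
    per_fold[f] <- 100 * mean(pred == y[hold])
  }
  structure(list(accuracy_pct = 100 * mean(correct),
                 per_fold_accuracy = per_fold,
                 fold_sizes = as.integer(table(factor(fold,
                                                      levels = seq_len(k)))),
                 k = as.integer(k),
                 model_spec = model,
                 rng_seed = as.integer(rng_seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold: accuracy %.2f%% (folds %.1f-%.1f%%)\n",
              x$model_spec$family, x$k, x$accuracy_pct,
              min(x$per_fold_accuracy), max(x$per_fold_accuracy)))
  invisible(x)
}

#' Predicted germination percentage of a subsample
#'
#' @param model_handle a fitted `spec_classifier`.
#' @param subsample a non-empty [spectral_dataset()] on the same band grid.
#' @return `100 * (# profiles predicted germinating) / n_profiles`.
#' @export
predict_germination_pct <- function(model_handle, subsample) {
  stopifnot(inherits(subsample, "spectral_dataset"))
  if (n_profiles(subsample) == 0L) stop("empty subsample", call. = FALSE)
  100 * mean(predict(model_handle, subsample) == 1L)
}

#' Root mean square error between percentage vectors
#'
#' @param predicted,known equal-length non-empty numeric vectors (percent).
#' @return `sqrt(mean((predicted - known)^2))`.
#' @export
rmse <- function(predicted, known) {
  if (length(predicted) == 0L) stop("empty input", call. = FALSE)
  if (length(predicted) != length(known)) {
    stop("predicted and known must have equal length", call. = FALSE)
  }
  sqrt(mean((predicted - known)^2))
}

#' Validate a trained model on labeled subsamples
#'
#' Applies a fitted classifier to each validation subsample, compares the
#' predicted germination percentage with the known (seed-company) value,
#' and summarizes by RMSE.  By default every supplied subsample enters the
#' RMSE (training-derived and independent alike, as plotted in the
#' motivating study); `restrict_independent = TRUE` limits the RMSE to
#' independent subsamples only.
#'
#' @param model_handle a fitted `spec_classifier`.
#' @param subsamples a list; each element a list with fields `dataset`
#'   (a [spectral_dataset()]), `known_pct` (percent), `is_training`
#'   (logical), and optionally `subsample_id` and `day`.
#' @param restrict_independent include only `is_training = FALSE` rows in
#'   the RMSE (default `FALSE`).
#' @return a `validation_report`: `rows` data.frame (subsample_id, day,
#'   n_seeds, predicted_germination_pct, known_germination_pct,
#'   is_training_subsample) and `rmse`.
#' @export
validate_subsamples <- function(model_handle, subsamples,
                                restrict_independent = FALSE) {
  if (!length(subsamples)) stop("need at least one subsample", call. = FALSE)
  rows <- do.call(rbind, lapply(seq_along(subsamples), function(i) {
    s <- subsamples[[i]]
    data.frame(
      subsample_id = if (!is.null(s$subsample_id)) s$subsample_id else
        as.character(i),
      day = if (!is.null(s$day)) as.character(s$day) else NA_character_,
      n_seeds = n_profiles(s$dataset),
      predicted_germination_pct =
        predict_germination_pct(model_handle, s$dataset),
      known_germination_pct = as.numeric(s$known_pct),
      is_training_subsample = isTRUE(s$is_training),
      stringsAsFactors = FALSE)
  }))
  use <- if (restrict_independent) !rows$is_training_subsample else
    rep(TRUE, nrow(rows))
  if (!any(use)) stop("no subsamples left for RMSE after restriction",
                      call. = FALSE)
  structure(list(rows = rows,
                 rmse = rmse(rows$predicted_germination_pct[use],
                             rows$known_germination_pct[use]),
                 restrict_independent = restrict_independent,
                 model_spec = model_handle$model),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: RMSE %.2f over %d subsamples%s\n",
              x$model_spec$family, x$rmse, nrow(x$rows),
              if (x$restrict_independent) " (independent only)" else ""))
  print(x$rows, row.names = FALSE)
  invisible(x)
}
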
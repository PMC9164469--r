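#' Parsimony guard against over-fitting (Hughes phenomenon)
#'
#' The maximum number of explanatory spectral bands considered safe for a
#' classification model: `max_bands = floor((objects - classes) / 3)`.
#' For example, 400 objects in 4 classes cap the band count at 132.
#'
#' @param objects number of objects (observations); must exceed `classes`.
#' @param classes number of classes, `>= 2`.
#' @return a `parsimony_guard` list: `objects`, `classes`, `max_bands`.
#' @export
parsimony_guard <- function(objects, classes = 2L) {
  objects <- as.integer(objects); classes <- as.integer(classes)
  if (classes < 2L) stop("need at least 2 classes", call. = FALSE)
  if (objects <= classes) {
    stop("objects must exceed the number of classes", call. = FALSE)
  }
  structure(list(objects = objects, classes = classes,
                 max_bands = (objects - classes) %/% 3L),
            class = "parsimony_guard")
}

#' @export
print.parsimony_guard <- function(x, ...) {
  cat(sprintf("<parsimony_guard> %d objects, %d classes: max %d bands\n",
              x$objects, x$classes, x$max_bands))
  invisible(x)
}

.sweep_seeds <- function(plan, level, replicate) {
  derive_seed(plan$rng_seed, "manipulation", plan$kind,
              sprintf("%.10g", level), replicate)
}

#' Run a manipulation sweep
#'
#' For each level of the plan (times replicates), applies the manipulation
#' to a fresh copy of the dataset using a level- and replicate-specific
#' substream seed, then measures k-fold cross-validated accuracy.  The
#' fold assignment seed is held constant across levels, so the level-0
#' point equals the unmanipulated baseline exactly.
#'
#' @param dataset a [spectral_dataset()].
#' @param plan a [manipulation_plan()].
#' @param model a [model_spec()].
#' @param k fold count (default 10).
#' @return an `accuracy_curve`: `points` data.frame (`level_pct`,
#'   `accuracy_pct`; replicate-averaged), `raw` data.frame with one row per
#'   level x replicate, plus `kind`, `model_spec`, `rng_seed`.
#' @export
run_sweep <- function(dataset, plan, model, k = 10L) {
  stopifnot(inherits(plan, "manipulation_plan"))
  curves <- run_sweep_multi(dataset, plan, list(model), k)
  curves[[1L]]
}

# Sweep several families over IDENTICAL perturbed datasets per level
# (shared substream seeds) -- the basis for a meaningful paired comparison.
run_sweep_multi <- function(dataset, plan, models, k = 10L) {
  stopifnot(inherits(dataset, "spectral_dataset"),
            inherits(plan, "manipulation_plan"))
  cv_seed <- derive_seed(plan$rng_seed, "cv", plan$kind)
  grid <- expand.grid(replicate = seq_len(plan$replicates),
                      level = plan$levels)
  raw <- vector("list", length(models))
  for (i in seq_len(nrow(grid))) {
    lev <- grid$level[i]; rep_i <- grid$replicate[i]
    perturbed <- apply_manipulation(dataset, plan$kind, lev,
                                    .sweep_seeds(plan, lev, rep_i))
    for (m in seq_along(models)) {
      cv <- cross_validated_accuracy(perturbed, models[[m]], k = k,
                                     rng_seed = cv_seed)
      raw[[m]] <- rbind(raw[[m]],
                        data.frame(level_pct = 100 * lev,
                                   replicate = rep_i,
                                   accuracy_pct = cv$accuracy_pct))
    }
  }
  lapply(seq_along(models), function(m) {
    r <- raw[[m]]
    pts <- stats::aggregate(accuracy_pct ~ level_pct, data = r, FUN = mean)
    pts <- pts[order(pts$level_pct), , drop = FALSE]
    structure(list(kind = plan$kind,
                   points = data.frame(level_pct = pts$level_pct,
                                       accuracy_pct = pts$accuracy_pct),
                   raw = r,
                   model_spec = models[[m]],
                   k = as.integer(k),
                   rng_seed = plan$rng_seed),
              class = "accuracy_curve")
  })
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat(sprintf("<accuracy_curve> %s, %s, %d-fold CV\n", x$kind,
              x$model_spec$family, x$k))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Ordinary least squares of accuracy on manipulation level
#'
#' Fits `accuracy_pct ~ level_pct` over the (replicate-averaged) points of
#' a curve and reports slope (percentage points accuracy per percentage
#' point of level), intercept and adjusted R^2
#' (`1 - (1 - R^2)(n - 1)/(n - 2)` for the simple regression).
#'
#' @param curve an `accuracy_curve` from [run_sweep()], or a data.frame
#'   with columns `level_pct` and `accuracy_pct`; `>= 3` points.
#' @return a `regression_summary`: `slope`, `intercept`, `adjusted_r2`,
#'   `r2`, `n_points`.
#' @export
fit_linear <- function(curve) {
  pts <- if (inherits(curve, "accuracy_curve")) curve$points else
    as.data.frame(curve)
  stopifnot(all(c("level_pct", "accuracy_pct") %in% names(pts)))
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::var(pts$level_pct) == 0) {
    stop("all levels identical: zero variance in x", call. = FALSE)
  }
  fit <- lm(accuracy_pct ~ level_pct, data = pts)
  r2 <- summary(fit)$r.squared
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r2 = r2,
                 adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
                 n_points = n),
            class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf(paste0("<regression_summary> slope = %.4f, intercept = %.2f, ",
                     "adjusted R^2 = %.4f (n = %d)\n"),
              x$slope, x$intercept, x$adjusted_r2, x$n_points))
  invisible(x)
}

#' Paired t-test between two accuracy vectors
#'
#' Textbook paired t: `d = x - y`, `t = mean(d) / (sd(d)/sqrt(n))`,
#' `df = n - 1`, two-sided p from the t distribution.  Pairing is by
#' manipulation level.
#'
#' @param x,y equal-length numeric vectors, `n >= 2`.
#' @return a `paired_test_result`: `t_statistic`, `df`, `p_value`,
#'   `mean_difference`, `n_pairs`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  s <- sd(d)
  if (s == 0) stop("degenerate variance: all paired differences equal",
                   call. = FALSE)
  t_stat <- mean(d) / (s / sqrt(n))
  structure(list(t_statistic = t_stat,
                 df = n - 1L,
                 p_value = 2 * pt(-abs(t_stat), df = n - 1L),
                 mean_difference = mean(d),
                 n_pairs = n),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("<paired_test_result> df = %d, t = %.3f, p-value = %.3g\n",
              x$df, x$t_statistic, x$p_value))
  invisible(x)
}

#' Sweep two classifier families and compare them
#'
#' Both families are swept over identical perturbed datasets per level
#' (shared manipulation substream seeds and fold assignment), then compared
#' by a paired t-test on the level-averaged accuracy vectors
#' (`x` = first family, `y` = second).  A degenerate paired test (zero
#' variance of the differences) is flagged rather than thrown.
#'
#' @param dataset a [spectral_dataset()].
#' @param plan a [manipulation_plan()].
#' @param k fold count (default 10).
#' @param families character vector of two families (default LDA, SVM).
#' @return list with `curves` (named list of `accuracy_curve`), `test`
#'   (a `paired_test_result` or `NULL`), `degenerate` flag.
#' @export
compare_families <- function(dataset, plan, k = 10L,
                             families = c("lda", "svm_linear")) {
  stopifnot(length(families) == 2L)
  models <- lapply(families, model_spec)
  curves <- run_sweep_multi(dataset, plan, models, k)
  names(curves) <- families
  x <- curves[[1L]]$points$accuracy_pct
  y <- curves[[2L]]$points$accuracy_pct
  test <- tryCatch(paired_t_test(x, y), error = function(e) NULL)
  list(curves = curves, test = test, degenerate = is.null(test))
}
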
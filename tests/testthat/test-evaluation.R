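test_that("both families score 100% on well-separated classes", {
  ds <- make_separable_dataset(30L)
  for (fam in c("lda", "svm_linear")) {
    cv <- cross_validated_accuracy(ds, model_spec(fam), k = 10L,
                                   rng_seed = 1L)
    expect_equal(cv$accuracy_pct, 100)
    expect_equal(cv$k, 10L)
    expect_length(cv$per_fold_accuracy, 10L)
  }
})

test_that("pooled accuracy equals the fold-size-weighted mean, exactly", {
  ds <- generate_spectra(small_config(n_per_sub = 60L, n_bands = 10L,
                                      delta = 0.01, rng_seed = 3L))
  cv <- cross_validated_accuracy(ds, model_spec("lda"), k = 7L,
                                 rng_seed = 2L)
  weighted <- sum(cv$per_fold_accuracy * cv$fold_sizes) / sum(cv$fold_sizes)
  expect_equal(cv$accuracy_pct, weighted, tolerance = 1e-12)
  expect_equal(sum(cv$fold_sizes), n_profiles(ds))
})

test_that("CV is deterministic given (dataset, model, k, seed)", {
  ds <- generate_spectra(small_config(n_per_sub = 40L, n_bands = 8L,
                                      rng_seed = 6L))
  a <- cross_validated_accuracy(ds, model_spec("lda"), rng_seed = 42L)
  b <- cross_validated_accuracy(ds, model_spec("lda"), rng_seed = 42L)
  expect_identical(a, b)
  c_ <- cross_validated_accuracy(ds, model_spec("lda"), rng_seed = 43L)
  expect_false(identical(a$per_fold_accuracy, c_$per_fold_accuracy))
})

test_that("accuracy sits at chance when the class effect is absent", {
  # delta = 0: labels carry no signal; mean CV accuracy over 20 generator
  # seeds should be within 50 +/- 3 percentage points.
  accs <- vapply(1:20, function(s) {
    ds <- generate_spectra(small_config(n_per_sub = 60L, n_bands = 10L,
                                        delta = 0, rng_seed = s))
    cross_validated_accuracy(ds, model_spec("lda"), rng_seed = s)$accuracy_pct
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 3)

  # and pooled correctness is binomially indistinguishable from 50%
  ds <- generate_spectra(small_config(n_per_sub = 100L, n_bands = 10L,
                                      delta = 0, rng_seed = 31L))
  for (fam in c("lda", "svm_linear")) {
    cv <- cross_validated_accuracy(ds, model_spec(fam), rng_seed = 31L)
    n <- n_profiles(ds)
    bt <- stats::binom.test(round(cv$accuracy_pct / 100 * n), n, 0.5)
    expect_gt(bt$p.value, 0.001)
  }
})

test_that("CV rejects degenerate inputs", {
  ds <- make_separable_dataset(5L)
  expect_error(cross_validated_accuracy(ds, model_spec("lda"), k = 10L),
               "fewer than k")
  all1 <- spectral_dataset(c(1, 2), matrix(1, 12, 2),
                           paste0("o", 1:12), rep("s", 12), rep(1L, 12))
  expect_error(cross_validated_accuracy(all1, model_spec("lda")),
               "class")
})

test_that("train_full contract: band checks, parsimony hint, prediction", {
  ds <- make_separable_dataset(20L)
  fit <- train_full(ds, model_spec("lda"))
  expect_identical(predict(fit, ds), ds$meta$label)
  expect_error(predict(fit, ds$reflectance[, 1:3]), "expects 6 bands")
  other <- spectral_dataset(seq(400, 600, length.out = 6), matrix(1, 4, 6),
                            paste0("x", 1:4), rep("s", 4), rep_len(0:1, 4))
  expect_error(predict(fit, other), "band grid")

  # a band constant within groups makes the LDA covariance singular;
  # the error carries the parsimony-guard hint
  Xc <- ds$reflectance; Xc[, 2L] <- 500
  dsc <- spectral_dataset(ds$wavelengths, Xc, ds$meta$object_id,
                          ds$meta$subsample_id, ds$meta$label)
  expect_error(train_full(dsc, model_spec("lda")), "parsimony")

  # more bands than the parsimony rule allows -> warning
  wide <- make_constant_dataset(20L, n_bands = 30L)
  Xw <- wide$reflectance + withr::with_seed(8L, matrix(rnorm(600), 20, 30))
  wide <- spectral_dataset(wide$wavelengths, Xw, wide$meta$object_id,
                           wide$meta$subsample_id, wide$meta$label)
  expect_warning(train_full(wide, model_spec("svm_linear")), "parsimony")
})

test_that("a trained model generalizes to a fresh generator batch", {
  cfg <- small_config(n_per_sub = 300L, n_bands = 40L, delta = 0.004,
                      rng_seed = 21L)
  ds <- generate_spectra(cfg)
  cv <- cross_validated_accuracy(ds, model_spec("lda"), rng_seed = 21L)
  fit <- train_full(ds, model_spec("lda"))
  cfg2 <- cfg; cfg2$rng_seed <- 22L
  fresh <- generate_spectra(cfg2)
  acc <- 100 * mean(predict(fit, fresh) == fresh$meta$label)
  expect_lt(abs(acc - cv$accuracy_pct), 5)
})

test_that("predicted germination percentage is a simple proportion", {
  train <- make_separable_dataset(20L)
  fit <- train_full(train, model_spec("lda"))
  mk <- function(n1, n0) {
    sub <- make_separable_dataset(max(n1, n0))
    keep <- c(which(sub$meta$label == 0L)[seq_len(n0)],
              which(sub$meta$label == 1L)[seq_len(n1)])
    subset_profiles(sub, sort(keep))
  }
  expect_equal(predict_germination_pct(fit, mk(96L, 0L)), 100)
  expect_equal(predict_germination_pct(fit, mk(48L, 48L)), 50)
  expect_equal(predict_germination_pct(fit, mk(73L, 23L)), 100 * 73 / 96)
  expect_equal(predict_germination_pct(fit, mk(73L, 23L)), 76.0417,
               tolerance = 1e-4)
})

test_that("rmse matches its closed form and rejects bad input", {
  expect_equal(rmse(c(50, 60), c(50, 60)), 0)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt((9 + 16) / 2))
  expect_equal(rmse(c(3, 4), c(0, 0)), 3.53553, tolerance = 1e-5)
  expect_equal(rmse(80, 70), 10)
  expect_error(rmse(numeric(), numeric()), "empty")
  expect_error(rmse(1:3, 1:2), "equal length")
})

test_that("validate_subsamples reports one row per subsample and the RMSE", {
  train <- make_separable_dataset(30L)
  fit <- train_full(train, model_spec("svm_linear"))
  sub <- make_separable_dataset(48L)  # predicted exactly 50% germinating
  entries <- list(
    list(dataset = sub, known_pct = 50, is_training = TRUE,
         subsample_id = "t1", day = "day1"),
    list(dataset = sub, known_pct = 60, is_training = FALSE,
         subsample_id = "v1", day = "day2"),
    list(dataset = sub, known_pct = 40, is_training = FALSE,
         subsample_id = "v2", day = "day2"))
  rep_all <- validate_subsamples(fit, entries)
  expect_equal(nrow(rep_all$rows), 3L)
  expect_equal(rep_all$rows$predicted_germination_pct, rep(50, 3))
  # errors 0, -10, +10 over all three rows
  expect_equal(rep_all$rmse, sqrt(200 / 3))

  rep_ind <- validate_subsamples(fit, entries, restrict_independent = TRUE)
  expect_equal(rep_ind$rmse, 10)  # errors -10 and +10

  perfect <- validate_subsamples(fit, list(
    list(dataset = sub, known_pct = 50, is_training = FALSE)))
  expect_equal(perfect$rmse, 0)
  expect_error(validate_subsamples(fit, list()), "at least one")
})
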
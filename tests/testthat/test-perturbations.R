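test_that("manipulation plans validate their level grids", {
  p <- manipulation_plan("assignment_error")
  expect_length(p$levels, 12L)
  expect_equal(p$levels, c(0, 1, 2, 4, 6, 8, 10, 15, 20, 30, 40, 50) / 100)
  expect_length(manipulation_plan("spectral_noise")$levels, 8L)
  expect_length(manipulation_plan("size_reduction")$levels, 10L)

  expect_error(manipulation_plan("assignment_error", c(0, 0.2, 0.1)),
               "ascending")
  expect_error(manipulation_plan("assignment_error", c(0.1, 0.2)),
               "level 0")
  expect_error(manipulation_plan("assignment_error", c(0, 0.6)),
               "\\[0, 0.5\\]")
  expect_error(manipulation_plan("spectral_noise", c(0, 0.2)),
               "\\[0, 0.1\\]")
  expect_error(manipulation_plan("size_reduction", c(0, 0.95)),
               "\\[0, 0.9\\]")
})

test_that("flip_labels flips round(rate * n_c) per class, labels only", {
  ds <- make_constant_dataset(2000L)  # 1000 per class
  res <- flip_labels(ds, 0.06, rng_seed = 3L)
  expect_equal(nrow(res$flips), 120L)
  expect_equal(sum(res$flips$original_label == 0L), 60L)
  expect_equal(sum(res$flips$original_label == 1L), 60L)
  expect_true(all(res$flips$original_label != res$flips$new_label))
  # reflectance multiset untouched, balanced counts preserved exactly
  expect_identical(res$dataset$reflectance, ds$reflectance)
  expect_identical(class_counts(res$dataset), class_counts(ds))

  ds33 <- make_constant_dataset(66L)  # 33 per class
  expect_equal(nrow(flip_labels(ds33, 0.10, 1L)$flips), 6L)  # round(3.3) x 2

  res0 <- flip_labels(ds, 0, 1L)
  expect_dataset_equal(res0$dataset, ds)
  expect_equal(nrow(res0$flips), 0L)

  expect_error(flip_labels(ds, 0.6, 1L), "\\[0, 0.5\\]")
  all1 <- spectral_dataset(c(1, 2), matrix(1, 3, 2), c("a", "b", "c"),
                           rep("s", 3), c(1, 1, 1))
  expect_error(flip_labels(all1, 0.1, 1L), "non-empty")
})

test_that("unbalanced flips shift class counts by k0 - k1", {
  ds <- generate_spectra(small_config(n_per_sub = 50L, n_bands = 4L,
                                      rate = 0.8, rng_seed = 2L))
  cb <- class_counts(ds)
  res <- flip_labels(ds, 0.10, rng_seed = 9L)
  k0 <- round(0.10 * cb$n_class0); k1 <- round(0.10 * cb$n_class1)
  cb2 <- class_counts(res$dataset)
  expect_equal(cb2$n_class1, cb$n_class1 - k1 + k0)
  expect_equal(nrow(res$flips), k0 + k1)
})

test_that("re-flipping the logged objects restores the original labels", {
  ds <- make_noise_dataset(40L)
  res <- flip_labels(ds, 0.25, rng_seed = 12L)
  restored <- res$dataset
  idx <- match(res$flips$object_id, restored$meta$object_id)
  restored$meta$label[idx] <- 1L - restored$meta$label[idx]
  expect_identical(restored$meta$label, ds$meta$label)
})

test_that("spectral noise respects its uniform support", {
  ds <- make_constant_dataset(50000L, n_bands = 2L, value = 1000)  # 1e5 values
  out <- add_spectral_noise(ds, 0.02, rng_seed = 1L)
  expect_gte(min(out$reflectance), 980)
  expect_lte(max(out$reflectance), 1020)
  # mean of perturbed/original over 1e5 draws: within 3 sd of the U(-r, r)
  # mean, sd = r/sqrt(3)/sqrt(1e5)
  expect_lt(abs(mean(out$reflectance / 1000) - 1),
            3 * 0.02 / sqrt(3) / sqrt(1e5))
  expect_identical(out$meta, ds$meta)

  expect_dataset_equal(add_spectral_noise(ds, 0, 1L), ds)
  expect_error(add_spectral_noise(ds, -0.01, 1L), ">= 0")
})

test_that("noise draws pass a KS test against Uniform(-r, r)", {
  ds <- make_constant_dataset(5000L, n_bands = 2L, value = 1000)
  r <- 0.04
  out <- add_spectral_noise(ds, r, rng_seed = 8L)
  u <- as.vector(out$reflectance / ds$reflectance - 1)
  ks <- suppressWarnings(stats::ks.test(u, "punif", -r, r))
  expect_gt(ks$p.value, 0.001)
})

test_that("directional and windowed noise behave per contract", {
  ds <- make_constant_dataset(200L, n_bands = 10L, value = 1000)
  pos <- add_spectral_noise_directional(ds, 0.02, "positive", rng_seed = 2L)
  expect_gte(min(pos$reflectance), 1000)
  expect_lte(max(pos$reflectance), 1020)
  neg <- add_spectral_noise_directional(ds, 0.02, "negative", rng_seed = 2L)
  expect_gte(min(neg$reflectance), 980)
  expect_lte(max(neg$reflectance), 1000)

  win <- add_spectral_noise_directional(ds, 0.05, "both",
                                        band_window = c(520, 560),
                                        rng_seed = 4L)
  inside <- ds$wavelengths >= 520 & ds$wavelengths <= 560
  expect_identical(win$reflectance[, !inside], ds$reflectance[, !inside])
  expect_true(all(win$reflectance[, inside] != ds$reflectance[, inside]))

  both <- add_spectral_noise_directional(ds, 0.05, "both", rng_seed = 4L)
  expect_identical(both$reflectance,
                   add_spectral_noise(ds, 0.05, rng_seed = 4L)$reflectance)

  expect_error(add_spectral_noise_directional(ds, 0.02, "both",
                                              band_window = c(100, 200)),
               "no bands")
})

test_that("reduce_training removes round(f * n_c) per class, order kept", {
  ds <- make_constant_dataset(2000L)  # 1000 per class
  red <- reduce_training(ds, 0.10, rng_seed = 5L)
  cb <- class_counts(red)
  expect_equal(cb$n_class0, 900L)
  expect_equal(cb$n_class1, 900L)
  # sub-multiset of the input, original order preserved
  idx <- match(red$meta$object_id, ds$meta$object_id)
  expect_false(anyNA(idx))
  expect_true(!is.unsorted(idx, strictly = TRUE))
  expect_identical(red$reflectance, ds$reflectance[idx, ])

  red90 <- reduce_training(ds, 0.90, rng_seed = 5L)
  expect_equal(class_counts(red90)$n_class0, 100L)
  expect_equal(class_counts(red90)$n_class1, 100L)

  expect_dataset_equal(reduce_training(ds, 0, 1L), ds)
  tiny <- make_constant_dataset(10L)  # 5 per class
  expect_error(reduce_training(tiny, 0.95, 1L), "empty a class")
  expect_error(reduce_training(ds, 1, 1L), "\\[0, 1\\)")
})

test_that("all manipulations are pure given (dataset, level, seed)", {
  ds <- make_noise_dataset(60L, n_bands = 6L)
  cases <- list(c("assignment_error", 0.2), c("spectral_noise", 0.05),
                c("size_reduction", 0.5))
  for (cs in cases) {
    a <- apply_manipulation(ds, cs[1L], as.numeric(cs[2L]), rng_seed = 77L)
    b <- apply_manipulation(ds, cs[1L], as.numeric(cs[2L]), rng_seed = 77L)
    expect_dataset_equal(a, b)
    # level 0 is bit-identical to the input
    expect_identical(apply_manipulation(ds, cs[1L], 0, rng_seed = 77L), ds)
  }
})
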
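# Fixtures are built in code; nothing is read from disk.

# Two well-separated classes with a little deterministic within-class
# jitter (LDA needs non-zero within-group variance).
make_separable_dataset <- function(n_per_class = 30L, n_bands = 6L) {
  n <- 2L * n_per_class
  w <- seq(500, 600, length.out = n_bands)
  base <- rep(c(100, 200), each = n_per_class)
  jitter <- withr::with_seed(2024L, matrix(rnorm(n * n_bands), n, n_bands))
  spectral_dataset(w, base + jitter,
                   sprintf("obj%04d", seq_len(n)),
                   rep(c("s0", "s1"), each = n_per_class),
                   rep(0:1, each = n_per_class))
}

# Balanced two-class dataset with arbitrary (label-independent) spectra.
make_noise_dataset <- function(n_per_class = 30L, n_bands = 4L,
                               value = 1000, rng_seed = 99L) {
  n <- 2L * n_per_class
  w <- seq(432, 1025, length.out = n_bands)
  X <- withr::with_seed(rng_seed,
                        matrix(value * exp(rnorm(n * n_bands, 0, 0.05)),
                               n, n_bands))
  spectral_dataset(w, X,
                   sprintf("obj%04d", seq_len(n)),
                   rep("s1", n),
                   rep(0:1, each = n_per_class))
}

# Constant-value dataset (every reflectance equal), for noise-support checks.
make_constant_dataset <- function(n_profiles, n_bands = 2L, value = 1000) {
  spectral_dataset(seq(500, 600, length.out = n_bands),
                   matrix(value, n_profiles, n_bands),
                   sprintf("obj%06d", seq_len(n_profiles)),
                   rep("s1", n_profiles),
                   rep_len(0:1, n_profiles))
}

# Small, fast generator configuration for CV-level tests.
small_config <- function(n_per_sub = 120L, n_bands = 40L, delta = 0.0016,
                         rate = 0.5, rng_seed = 1L, ...) {
  generator_config(wavelengths = band_grid(n_bands),
                   subsamples = data.frame(
                     subsample_id = c("a", "b"),
                     n_seeds = c(n_per_sub, n_per_sub),
                     germination_rate = c(rate, rate)),
                   class_effect_amplitude = delta,
                   rng_seed = rng_seed, ...)
}

expect_dataset_equal <- function(a, b) {
  expect_identical(a$wavelengths, b$wavelengths)
  expect_identical(a$reflectance, b$reflectance)
  expect_identical(a$meta, b$meta)
}
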
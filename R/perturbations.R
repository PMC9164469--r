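# Rounding rule for per-class flip/removal counts: round-half-away-from-zero
# on rate * n_c (worked examples -- 60 of 1000 at 6%, 100 of 1000 at 10% --
# are exact integers under any rule; this one is fixed for reproducibility).
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

.manipulation_kinds <- c("assignment_error", "spectral_noise",
                         "size_reduction")

#' Default manipulation level grids
#'
#' The three standard grids: assignment error 0-50% (12 levels), spectral
#' noise ranges 0-10% (8 ranges), training-set reduction 0-90% (10 levels).
#'
#' @param kind one of `"assignment_error"`, `"spectral_noise"`,
#'   `"size_reduction"`.
#' @return numeric vector of levels as fractions.
#' @export
default_levels <- function(kind = .manipulation_kinds) {
  kind <- match.arg(kind)
  switch(kind,
         assignment_error = c(0, 1, 2, 4, 6, 8, 10, 15, 20, 30, 40, 50) / 100,
         spectral_noise   = c(0, 0.5, 1, 2, 4, 6, 8, 10) / 100,
         size_reduction   = c(0, 5, 10, 20, 30, 40, 50, 60, 75, 90) / 100)
}

#' Plan a training-data manipulation sweep
#'
#' @param kind manipulation kind (see [default_levels()]).
#' @param levels ordered fractions; must be sorted ascending, include 0, and
#'   lie in the kind's domain (flip `[0, 0.5]`, noise `[0, 0.10]`,
#'   reduction `[0, 0.90]`).
#' @param replicates independent random draws per level (default 1).
#' @param rng_seed integer master seed for the sweep.
#' @return a `manipulation_plan` list.
#' @export
manipulation_plan <- function(kind = .manipulation_kinds,
                              levels = default_levels(kind),
                              replicates = 1L, rng_seed = 1L) {
  kind <- match.arg(kind)
  levels <- as.numeric(levels)
  if (is.unsorted(levels, strictly = TRUE)) {
    stop("levels must be strictly ascending", call. = FALSE)
  }
  if (levels[1L] != 0) stop("level 0 (no manipulation) must be present",
                            call. = FALSE)
  upper <- c(assignment_error = 0.5, spectral_noise = 0.10,
             size_reduction = 0.90)[[kind]]
  if (any(levels < 0) || any(levels > upper)) {
    stop(sprintf("levels for %s must lie in [0, %g]", kind, upper),
         call. = FALSE)
  }
  stopifnot(replicates >= 1L)
  structure(list(kind = kind, levels = levels,
                 replicates = as.integer(replicates),
                 rng_seed = as.integer(rng_seed)),
            class = "manipulation_plan")
}

#' Inject class-assignment error
#'
#' Per class, `round(rate * n_c)` objects are drawn uniformly without
#' replacement and their labels inverted (non-germinating assigned to
#' germinating and vice versa), so the error is assigned separately and
#' equally to both classes and class balance is preserved when classes are
#' balanced.  Reflectance is untouched.
#'
#' @param dataset a [spectral_dataset()]; both classes must be non-empty.
#' @param rate flip fraction in `[0, 0.5]`.
#' @param rng_seed integer seed for the draw.
#' @return list with `dataset` (labels flipped) and `flips` (data.frame
#'   `object_id`, `original_label`, `new_label`; empty when `rate = 0`).
#' @export
flip_labels <- function(dataset, rate, rng_seed = 1L) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (rate < 0 || rate > 0.5) stop("rate must be in [0, 0.5]", call. = FALSE)
  lab <- dataset$meta$label
  idx0 <- which(lab == 0L); idx1 <- which(lab == 1L)
  if (!length(idx0) || !length(idx1)) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  k0 <- round_half_away(rate * length(idx0))
  k1 <- round_half_away(rate * length(idx1))
  flip_idx <- withr::with_seed(rng_seed, {
    c(if (k0 > 0L) idx0[sample.int(length(idx0), k0)] else integer(),
      if (k1 > 0L) idx1[sample.int(length(idx1), k1)] else integer())
  })
  new_lab <- lab
  new_lab[flip_idx] <- 1L - new_lab[flip_idx]
  out <- dataset
  out$meta$label <- new_lab
  list(dataset = out,
       flips = data.frame(object_id = dataset$meta$object_id[flip_idx],
                          original_label = lab[flip_idx],
                          new_label = new_lab[flip_idx],
                          stringsAsFactors = FALSE))
}

#' Add bounded stochastic spectral noise
#'
#' Each reflectance value `v` is replaced by `v * (1 + u)` with
#' `u ~ Uniform(-r, +r)` drawn independently per (profile, band) -- noise in
#' one band is independent of other bands and varies among seeds.  A range
#' `r = 0.02` maps a value of 1000 onto `[980, 1020]`.  Labels untouched.
#'
#' @param dataset a [spectral_dataset()].
#' @param noise_range relative range `r >= 0` (grid domain `[0, 0.10]`).
#' @param rng_seed integer seed.
#' @return a perturbed [spectral_dataset()].
#' @export
add_spectral_noise <- function(dataset, noise_range, rng_seed = 1L) {
  add_spectral_noise_directional(dataset, noise_range, sign = "both",
                                 band_window = NULL, rng_seed = rng_seed)
}

#' Directional / windowed spectral noise
#'
#' Variant supporting one-sided noise (systematic darkening or brightening)
#' and restriction to a wavelength window.  With `sign = "both"` and no
#' window it is stream-identical to [add_spectral_noise()].
#'
#' @param dataset a [spectral_dataset()].
#' @param noise_range relative range `r >= 0`.
#' @param sign `"both"` (`u ~ U(-r, r)`), `"negative"` (`U(-r, 0)`) or
#'   `"positive"` (`U(0, r)`).
#' @param band_window optional `c(lo, hi)` wavelength interval (nm); bands
#'   outside it are left unchanged.  `NULL` means all bands.
#' @param rng_seed integer seed.
#' @return a perturbed [spectral_dataset()].
#' @export
add_spectral_noise_directional <- function(dataset, noise_range,
                                           sign = c("both", "negative",
                                                    "positive"),
                                           band_window = NULL,
                                           rng_seed = 1L) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  sign <- match.arg(sign)
  if (noise_range < 0) stop("noise_range must be >= 0", call. = FALSE)
  in_window <- if (is.null(band_window)) {
    rep(TRUE, n_bands(dataset))
  } else {
    stopifnot(length(band_window) == 2L)
    dataset$wavelengths >= band_window[1L] &
      dataset$wavelengths <= band_window[2L]
  }
  if (!any(in_window)) stop("band window contains no bands", call. = FALSE)
  n <- n_profiles(dataset); d <- n_bands(dataset)
  lo <- switch(sign, both = -noise_range, negative = -noise_range,
               positive = 0)
  hi <- switch(sign, both = noise_range, negative = 0,
               positive = noise_range)
  u <- withr::with_seed(rng_seed, matrix(runif(n * d, lo, hi), n, d))
  u[, !in_window] <- 0
  out <- dataset
  out$reflectance <- dataset$reflectance * (1 + u)
  out
}

#' Reduce the training set, preserving class balance
#'
#' Per class, `round(f * n_c)` objects are removed uniformly without
#' replacement; the remaining profiles are untouched and keep their
#' original order.
#'
#' @param dataset a [spectral_dataset()].
#' @param fraction removal fraction `0 <= f < 1`; must leave at least one
#'   object per class.
#' @param rng_seed integer seed.
#' @return a reduced [spectral_dataset()].
#' @export
reduce_training <- function(dataset, fraction, rng_seed = 1L) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (fraction < 0 || fraction >= 1) {
    stop("fraction must be in [0, 1)", call. = FALSE)
  }
  lab <- dataset$meta$label
  idx0 <- which(lab == 0L); idx1 <- which(lab == 1L)
  k0 <- round_half_away(fraction * length(idx0))
  k1 <- round_half_away(fraction * length(idx1))
  if (length(idx0) - k0 < 1L || length(idx1) - k1 < 1L) {
    stop("reduction would empty a class", call. = FALSE)
  }
  drop_idx <- withr::with_seed(rng_seed, {
    c(if (k0 > 0L) idx0[sample.int(length(idx0), k0)] else integer(),
      if (k1 > 0L) idx1[sample.int(length(idx1), k1)] else integer())
  })
  if (!length(drop_idx)) return(dataset)
  subset_profiles(dataset, setdiff(seq_along(lab), drop_idx))
}

#' Apply one manipulation at one level
#'
#' Dispatcher used by sweeps: level 0 always returns the dataset unchanged
#' (bit-identical).
#'
#' @param dataset a [spectral_dataset()].
#' @param kind manipulation kind.
#' @param level fraction.
#' @param rng_seed integer seed.
#' @return a [spectral_dataset()].
#' @export
apply_manipulation <- function(dataset, kind = .manipulation_kinds, level,
                               rng_seed = 1L) {
  kind <- match.arg(kind)
  if (level == 0) return(dataset)
  switch(kind,
         assignment_error = flip_labels(dataset, level, rng_seed)$dataset,
         spectral_noise = add_spectral_noise(dataset, level, rng_seed),
         size_reduction = reduce_training(dataset, level, rng_seed))
}
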
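#' Construct a labeled spectral dataset
#'
#' The central container: one row per object (seed), one column per spectral
#' band, plus a binary germination label (`0` = non-germinating,
#' `1` = germinating) and a subsample (seed-lot) identifier per object.
#' Reflectance is kept in arbitrary relative-reflectance units; no `[0, 1]`
#' normalization is imposed.
#'
#' @param wavelengths numeric vector of band wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param reflectance numeric matrix, `n_profiles x n_bands`, finite and
#'   non-negative.
#' @param object_id character vector of unique object identifiers.
#' @param subsample_id character vector of subsample (seed lot) identifiers.
#' @param label integer vector in `{0, 1}`.
#' @param provenance optional free-text notes (variety, acquisition day).
#' @return an object of class `spectral_dataset` with fields `wavelengths`,
#'   `reflectance`, `meta` (data.frame: object_id, subsample_id, label) and
#'   `provenance`.
#' @export
spectral_dataset <- function(wavelengths, reflectance, object_id,
                             subsample_id, label, provenance = character()) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 2L) {
    stop("band grid needs at least 2 wavelengths", call. = FALSE)
  }
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be finite and strictly increasing", call. = FALSE)
  }
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  if (ncol(reflectance) != length(wavelengths)) {
    stop(sprintf("reflectance has %d columns but band grid has %d wavelengths",
                 ncol(reflectance), length(wavelengths)), call. = FALSE)
  }
  n <- nrow(reflectance)
  object_id <- as.character(object_id)
  subsample_id <- as.character(subsample_id)
  label <- as.integer(label)
  if (length(object_id) != n || length(subsample_id) != n ||
      length(label) != n) {
    stop("object_id, subsample_id and label must each have one entry per profile",
         call. = FALSE)
  }
  if (anyDuplicated(object_id)) {
    stop("object_id values must be unique", call. = FALSE)
  }
  if (n > 0L) {
    if (any(!is.finite(reflectance)) || any(reflectance < 0)) {
      bad <- which(!is.finite(reflectance) | reflectance < 0,
                   arr.ind = TRUE)[1L, ]
      stop(sprintf("non-finite or negative reflectance at row %d, band %g nm",
                   bad[1L], wavelengths[bad[2L]]), call. = FALSE)
    }
    if (any(!label %in% c(0L, 1L))) {
      bad <- which(!label %in% c(0L, 1L))[1L]
      stop(sprintf("label must be 0 or 1; offending row %d (object '%s')",
                   bad, object_id[bad]), call. = FALSE)
    }
  }
  dimnames(reflectance) <- NULL
  structure(
    list(wavelengths = wavelengths,
         reflectance = reflectance,
         meta = data.frame(object_id = object_id,
                           subsample_id = subsample_id,
                           label = label,
                           stringsAsFactors = FALSE),
         provenance = as.character(provenance)),
    class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cb <- class_counts(x)
  cat(sprintf(paste0("<spectral_dataset> %d profiles x %d bands ",
                     "[%.1f-%.1f nm]\n"),
              n_profiles(x), n_bands(x),
              min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("  classes: %d non-germinating (0), %d germinating (1); subsamples: %s\n",
              cb$n_class0, cb$n_class1,
              paste(unique(x$meta$subsample_id), collapse = ", ")))
  if (length(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Number of profiles / bands in a dataset
#' @param dataset a [spectral_dataset()].
#' @return integer count.
#' @export
n_profiles <- function(dataset) nrow(dataset$reflectance)

#' @rdname n_profiles
#' @export
n_bands <- function(dataset) length(dataset$wavelengths)

#' Per-class counts of a dataset
#'
#' @param dataset a [spectral_dataset()].
#' @return a `class_balance` list with integer fields `n_class0`
#'   (non-germinating) and `n_class1` (germinating).
#' @export
class_counts <- function(dataset) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  structure(list(n_class0 = sum(dataset$meta$label == 0L),
                 n_class1 = sum(dataset$meta$label == 1L)),
            class = "class_balance")
}

#' @export
print.class_balance <- function(x, ...) {
  cat(sprintf("<class_balance> n_class0 = %d, n_class1 = %d (total %d)\n",
              x$n_class0, x$n_class1, x$n_class0 + x$n_class1))
  invisible(x)
}

#' Subset a dataset by profile index
#'
#' Keeps profiles in their original order; used by the training-set
#' reduction manipulation and by cross-validation fold handling.
#'
#' @param dataset a [spectral_dataset()].
#' @param idx integer index vector (rows to keep).
#' @return a [spectral_dataset()].
#' @export
subset_profiles <- function(dataset, idx) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  idx <- as.integer(idx)
  spectral_dataset(dataset$wavelengths,
                   dataset$reflectance[idx, , drop = FALSE],
                   dataset$meta$object_id[idx],
                   dataset$meta$subsample_id[idx],
                   dataset$meta$label[idx],
                   dataset$provenance)
}

.required_cols <- c("object_id", "subsample_id", "label")

#' Read labeled reflectance profiles from CSV
#'
#' Expects a header with columns `object_id`, `subsample_id`, `label`, then
#' one column per spectral band named by its wavelength in nm (e.g. "432.0").
#' Band order is taken from header order; wavelengths are parsed from the
#' band column names.
#'
#' @param path path to a CSV file.
#' @param provenance optional free-text notes attached to the dataset.
#' @return a validated [spectral_dataset()].
#' @export
read_profiles_csv <- function(path, provenance = character()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, colClasses = "character", header = TRUE,
                          sep = ",", data.table = TRUE, showProgress = FALSE)
  missing <- setdiff(.required_cols, names(dt))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  band_cols <- setdiff(names(dt), .required_cols)
  if (length(band_cols) < 2L) {
    stop("need at least 2 band columns", call. = FALSE)
  }
  wavelengths <- suppressWarnings(as.numeric(band_cols))
  if (any(is.na(wavelengths))) {
    stop("band column names must be numeric wavelengths; offending column '",
         band_cols[which(is.na(wavelengths))[1L]], "'", call. = FALSE)
  }
  lab_chr <- dt[["label"]]
  bad <- which(!lab_chr %in% c("0", "1"))
  if (length(bad)) {
    stop(sprintf("label must be 0 or 1; offending row %d (object '%s') has label '%s'",
                 bad[1L], dt[["object_id"]][bad[1L]], lab_chr[bad[1L]]),
         call. = FALSE)
  }
  refl <- matrix(NA_real_, nrow(dt), length(band_cols))
  for (j in seq_along(band_cols)) {
    v <- suppressWarnings(as.numeric(dt[[band_cols[j]]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("non-numeric reflectance at row %d, column '%s' (value '%s')",
                   i, band_cols[j], dt[[band_cols[j]]][i]), call. = FALSE)
    }
    refl[, j] <- v
  }
  spectral_dataset(wavelengths, refl, dt[["object_id"]],
                   dt[["subsample_id"]], as.integer(lab_chr), provenance)
}

#' Write a dataset to CSV
#'
#' Inverse of [read_profiles_csv()]: values are serialized with 17
#' significant digits so the round trip is exact (field-by-field identity).
#'
#' @param dataset a [spectral_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  band_names <- sprintf("%.17g", dataset$wavelengths)
  n <- n_profiles(dataset)
  cols <- c(list(object_id = dataset$meta$object_id,
                 subsample_id = dataset$meta$subsample_id,
                 label = as.character(dataset$meta$label)),
            stats::setNames(
              lapply(seq_len(n_bands(dataset)), function(j) {
                if (n == 0L) character() else
                  sprintf("%.17g", dataset$reflectance[, j])
              }),
              band_names))
  dt <- data.table::as.data.table(cols)
  ok <- tryCatch({
    data.table::fwrite(dt, path, quote = FALSE, sep = ",")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}
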
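#' Spectral dataset container
#'
#' A `spectral_dataset` holds a collection of ATR-FTIR absorbance spectra on
#' a shared wavenumber grid, together with per-sample metadata. The grid is
#' stored in descending wavenumber order (instrument convention, e.g.
#' 4000 -> 600 or 1800 -> 900 cm-1); readers accept either direction and
#' normalize.
#'
#' @param wavenumbers strictly monotone numeric grid in cm-1.
#' @param absorbance numeric matrix, one row per wavenumber, one column per
#'   sample; column names are sample ids.
#' @param metadata tibble with one row per sample: `sample_id`,
#'   `temperature_C`, `age_class` (day index as character, or
#'   `"EMPTY_PUPARIUM"` for the terminal post-eclosion class), `replicate`.
#' @return a `spectral_dataset` object.
#' @export
spectral_dataset <- function(wavenumbers, absorbance, metadata) {
  absorbance <- as.matrix(absorbance)
  if (length(wavenumbers) != nrow(absorbance)) {
    abort("wavenumber grid and absorbance rows differ in length")
  }
  d <- diff(wavenumbers)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    abort("wavenumber grid must be strictly monotone")
  }
  if (length(d) && all(d > 0)) {           # normalize to descending
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[rev(seq_len(nrow(absorbance))), , drop = FALSE]
  }
  if (anyNA(absorbance)) abort("absorbance values must not be missing")
  metadata <- as_tibble(metadata)
  need <- c("sample_id", "temperature_C", "age_class", "replicate")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) {
    abort(paste0("metadata lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(metadata$sample_id)) {
    dup <- unique(metadata$sample_id[duplicated(metadata$sample_id)])
    abort(paste0("duplicated sample_id: ", paste(dup, collapse = ", ")))
  }
  if (is.null(colnames(absorbance))) {
    if (ncol(absorbance) != nrow(metadata)) {
      abort("absorbance columns and metadata rows differ in number")
    }
    colnames(absorbance) <- metadata$sample_id
  }
  extra <- setdiff(colnames(absorbance), metadata$sample_id)
  if (length(extra)) {
    abort(paste0("sample(s) missing from metadata: ",
                 paste(extra, collapse = ", ")))
  }
  unmatched <- setdiff(metadata$sample_id, colnames(absorbance))
  if (length(unmatched)) {
    warn(paste0("metadata rows without spectra are dropped: ",
                paste(unmatched, collapse = ", ")))
    metadata <- metadata[metadata$sample_id %in% colnames(absorbance), ]
  }
  metadata <- metadata[match(colnames(absorbance), metadata$sample_id), ]
  metadata$age_class <- as.character(metadata$age_class)
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 absorbance = absorbance,
                 metadata = metadata),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d wavenumbers (%g-%g cm-1)\n",
              ncol(x$absorbance), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  cls <- table(x$metadata$age_class)
  cat("age classes:", paste(sprintf("%s(%d)", names(cls), cls),
                            collapse = " "), "\n")
  invisible(x)
}

#' @export
n_samples <- function(ds) ncol(ds$absorbance)

#' Long-format view of a spectral dataset
#'
#' @param x a `spectral_dataset`.
#' @param ... unused.
#' @return a tibble with columns `sample_id`, `wavenumber_cm1`,
#'   `absorbance` and the sample metadata, one row per point.
#' @exportS3Method tibble::as_tibble
#' @export
as_tibble.spectral_dataset <- function(x, ...) {
  long <- tibble(
    sample_id = rep(colnames(x$absorbance), each = length(x$wavenumbers)),
    wavenumber_cm1 = rep(x$wavenumbers, times = ncol(x$absorbance)),
    absorbance = as.vector(x$absorbance))
  left_join(long, x$metadata, by = "sample_id")
}

#' @rdname as_tibble.spectral_dataset
#' @exportS3Method generics::tidy
#' @export
tidy.spectral_dataset <- function(x, ...) as_tibble.spectral_dataset(x)

#' Plot the spectra of a dataset
#'
#' @param object a `spectral_dataset`.
#' @param colour_by metadata column mapped to line colour.
#' @param ... unused.
#' @return a ggplot with wavenumber on a reversed x axis (spectroscopy
#'   convention).
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.spectral_dataset <- function(object, colour_by = "age_class", ...) {
  long <- as_tibble(object)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$wavenumber_cm1, y = .data$absorbance,
    group = .data$sample_id, colour = .data[[colour_by]])) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)), y = "Absorbance")
}

#' Read spectra from a wide CSV plus a metadata sidecar
#'
#' @param path CSV whose first column is the wavenumber grid and remaining
#'   columns are one sample each (header = sample id).
#' @param metadata_path sidecar CSV keyed by `sample_id`, with columns
#'   `sample_id,temperature_C,age_class,replicate`.
#' @return a [spectral_dataset()]. Spectra without a metadata row, duplicate
#'   sample ids, or a non-monotone grid raise an error naming the offender.
#' @export
read_spectra <- function(path, metadata_path) {
  # parse numbers via base strtod (correctly rounded) so that reading back
  # a file written by write_spectra() is bit-exact
  wide <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  wide <- dplyr::mutate(wide, across(everything(), as.numeric))
  if (ncol(wide) < 2) abort("spectra file needs a grid column and >=1 sample")
  meta <- readr::read_csv(metadata_path, col_types = readr::cols(
    sample_id = readr::col_character(),
    temperature_C = readr::col_double(),
    age_class = readr::col_character(),
    replicate = readr::col_integer()), progress = FALSE)
  spectral_dataset(wavenumbers = wide[[1]],
                   absorbance = as.matrix(wide[, -1, drop = FALSE]),
                   metadata = meta)
}

#' Write a spectral dataset to a wide CSV plus metadata sidecar
#'
#' Inverse of [read_spectra()]; a write-then-read round trip preserves every
#' value.
#'
#' @param ds a `spectral_dataset`.
#' @inheritParams read_spectra
#' @return `ds`, invisibly.
#' @export
write_spectra <- function(ds, path, metadata_path) {
  wide <- bind_cols(tibble(wavenumber_cm1 = ds$wavenumbers),
                    as_tibble(as.data.frame(ds$absorbance)))
  # %.17g guarantees binary round trips; readr's shortest-representation
  # writer can lose the last ulp
  wide <- dplyr::mutate(wide, across(everything(), ~sprintf("%.17g", .x)))
  readr::write_csv(wide, path)
  readr::write_csv(ds$metadata, metadata_path)
  invisible(ds)
}
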
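#' Crop a dataset to the fingerprint region
#'
#' Retains exactly the grid points with `lo <= wavenumber <= hi` (closed
#' interval). The 1800--900 cm-1 fingerprint window carries the amide,
#' lipid-ester and carbohydrate/phosphate bands that change over puparial
#' development; everything outside it is discarded before analysis.
#'
#' @param ds a [spectral_dataset()].
#' @param lo,hi window bounds in cm-1.
#' @return the cropped `spectral_dataset`; metadata untouched.
#' @export
crop_fingerprint <- function(ds, lo = 900, hi = 1800) {
  if (lo > hi) abort("crop bounds out of order (lo > hi)")
  keep <- ds$wavenumbers >= lo & ds$wavenumbers <= hi
  if (!any(keep)) {
    abort(sprintf("no grid points in [%g, %g] cm-1", lo, hi))
  }
  spectral_dataset(ds$wavenumbers[keep],
                   ds$absorbance[keep, , drop = FALSE],
                   ds$metadata)
}

# Central Savitzky-Golay weights (value of the local least-squares
# polynomial fit at the window centre). Taken from the filter matrix of
# signal::sgolay; an independent least-squares oracle checks them in the
# test suite.
savgol_kernel <- function(window, polyorder) {
  m <- signal::sgolay(p = polyorder, n = window)
  as.numeric(m[(window + 1) / 2, ])
}

# Apply a symmetric convolution kernel with mirror padding at the edges.
convolve_mirror <- function(y, kernel) {
  h <- (length(kernel) - 1) / 2
  pad <- c(y[(h + 1):2], y, y[(length(y) - 1):(length(y) - h)])
  out <- stats::filter(pad, kernel, sides = 2)
  as.numeric(out[(h + 1):(h + length(y))])
}

#' Savitzky-Golay smoothing
#'
#' Replaces each point by the centre value of a least-squares polynomial fit
#' over a sliding window ("smoothing point 5" = a 5-point window; the
#' default quadratic is the standard order for so short a window). A
#' polynomial of the fitted order is reproduced exactly at every interior
#' point; edges are handled by mirror padding, which keeps the output the
#' same length at the cost of a small bias within `window %/% 2` points of
#' each end.
#'
#' @param x a numeric spectrum or a [spectral_dataset()] (applied per
#'   sample).
#' @param window odd window length, `> polyorder`.
#' @param polyorder polynomial order of the local fit.
#' @return smoothed object of the same type.
#' @export
savgol_smooth <- function(x, window = 5, polyorder = 2) {
  if (window %% 2 == 0) abort("Savitzky-Golay window must be odd")
  if (window <= polyorder) abort("window must exceed the polynomial order")
  kern <- savgol_kernel(window, polyorder)
  if (inherits(x, "spectral_dataset")) {
    if (length(x$wavenumbers) < window) {
      abort("spectrum shorter than the smoothing window")
    }
    x$absorbance <- apply(x$absorbance, 2, convolve_mirror, kernel = kern)
    return(x)
  }
  if (length(x) < window) abort("spectrum shorter than the smoothing window")
  convolve_mirror(as.numeric(x), kern)
}

#' Standard normal variate normalization
#'
#' Centers each spectrum to mean 0 and scales it to unit sample standard
#' deviation (n-1 denominator). SNV removes multiplicative gain and additive
#' offset differences between spectra -- the dominant nuisance variation in
#' ATR contact measurements -- and makes the whole preprocessing chain
#' invariant to affine transformations of the raw absorbances.
#'
#' @param x a numeric spectrum or a [spectral_dataset()] (applied per
#'   sample).
#' @return normalized object of the same type.
#' @export
snv_normalize <- function(x) {
  one <- function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      abort("SNV undefined for a constant spectrum (zero variance)")
    }
    (v - mean(v)) / s
  }
  if (inherits(x, "spectral_dataset")) {
    x$absorbance <- apply(x$absorbance, 2, one)
    return(x)
  }
  one(as.numeric(x))
}

#' Baseline correction
#'
#' The default `"linear_endpoints"` method subtracts the straight line
#' through the first and last grid points, anchoring both ends of the
#' corrected spectrum at exactly zero; it is fully deterministic and
#' reproducible. `"als"` fits an asymmetric-least-squares baseline
#' (smoothness `lambda`, asymmetry `p`) for curved backgrounds.
#'
#' @param x a numeric spectrum or a [spectral_dataset()] (applied per
#'   sample).
#' @param method `"linear_endpoints"` or `"als"`.
#' @param lambda,p ALS smoothness and asymmetry parameters.
#' @return baseline-corrected object of the same type.
#' @export
baseline_correct <- function(x, method = c("linear_endpoints", "als"),
                             lambda = 1e5, p = 0.01) {
  method <- match.arg(method)
  one <- function(v) {
    if (length(v) < 2) abort("baseline correction needs >= 2 points")
    if (method == "linear_endpoints") {
      n <- length(v)
      base <- v[1] + (v[n] - v[1]) * (seq_len(n) - 1) / (n - 1)
      v - base
    } else {
      v - als_baseline(v, lambda = lambda, p = p)
    }
  }
  if (inherits(x, "spectral_dataset")) {
    x$absorbance <- apply(x$absorbance, 2, one)
    return(x)
  }
  one(as.numeric(x))
}

# Asymmetric least squares baseline (Eilers-Boelens): penalized smoothing
# with weights p for points above the baseline and 1-p below, iterated to
# convergence.
als_baseline <- function(y, lambda = 1e5, p = 0.01, maxit = 10) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  P <- lambda * crossprod(D)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(maxit)) {
    z <- solve(diag(w) + P, w * y)
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  z
}

#' Mean centering across samples
#'
#' Subtracts the per-wavenumber mean over all samples, so every column
#' (wavenumber) of the result averages to zero. Centering is the last
#' preprocessing stage and the state PCA expects.
#'
#' @param ds a [spectral_dataset()] with at least two samples.
#' @return the centered `spectral_dataset`.
#' @export
mean_center <- function(ds) {
  if (ncol(ds$absorbance) < 2) {
    abort("mean centering needs >= 2 samples")
  }
  ds$absorbance <- ds$absorbance - rowMeans(ds$absorbance)
  ds
}

#' Average replicate spectra within groups
#'
#' Collapses each (temperature, age class) group -- by default the five
#' replicate measurements of one sampling time point -- to its pointwise
#' mean spectrum, mirroring the acquisition protocol in which five spectra
#' are combined into one averaged spectrum per sample.
#'
#' @param ds a [spectral_dataset()].
#' @param group_keys metadata columns defining the groups.
#' @return a `spectral_dataset` with one spectrum per group; the attribute
#'   `"group_sizes"` logs how many spectra each group averaged.
#' @export
average_replicates <- function(ds,
                               group_keys = c("temperature_C", "age_class")) {
  meta <- ds$metadata
  key <- do.call(paste, c(meta[group_keys], sep = "_"))
  groups <- unique(key)
  avg <- vapply(groups, function(g) {
    rowMeans(ds$absorbance[, key == g, drop = FALSE])
  }, numeric(length(ds$wavenumbers)))
  new_meta <- meta[match(groups, key), c("sample_id", group_keys)]
  new_meta$sample_id <- paste0("avg_", gsub("[^0-9A-Za-z_.-]", "", groups))
  for (col in setdiff(c("temperature_C", "age_class"), group_keys)) {
    new_meta[[col]] <- meta[[col]][match(groups, key)]
  }
  new_meta$replicate <- 1L
  colnames(avg) <- new_meta$sample_id
  out <- spectral_dataset(ds$wavenumbers, avg, new_meta)
  attr(out, "group_sizes") <- tibble(group = groups,
                                     n = as.integer(table(key)[groups]))
  out
}

#' Preprocessing configuration
#'
#' @param crop numeric `c(lo, hi)` fingerprint window in cm-1, or `NULL` to
#'   skip cropping.
#' @param savgol apply Savitzky-Golay smoothing?
#' @param savgol_window,savgol_polyorder smoothing window and polynomial
#'   order.
#' @param snv apply standard normal variate scaling?
#' @param baseline `"linear_endpoints"`, `"als"`, or `"none"`.
#' @param als_lambda,als_p ALS baseline parameters.
#' @param center mean-center across samples?
#' @param average `"before"` collapses replicates to per-group averages
#'   before the chain (the acquisition-time protocol and the default),
#'   `"after"` averages the preprocessed spectra, `"none"` keeps all
#'   replicates (required when replicates feed a train/validation split).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(crop = c(900, 1800),
                              savgol = TRUE, savgol_window = 5,
                              savgol_polyorder = 2,
                              snv = TRUE,
                              baseline = c("linear_endpoints", "als", "none"),
                              als_lambda = 1e5, als_p = 0.01,
                              center = TRUE,
                              average = c("before", "none", "after")) {
  structure(list(crop = crop, savgol = savgol,
                 savgol_window = savgol_window,
                 savgol_polyorder = savgol_polyorder, snv = snv,
                 baseline = match.arg(baseline),
                 als_lambda = als_lambda, als_p = als_p,
                 center = center, average = match.arg(average)),
            class = "preprocess_config")
}

#' Run the full preprocessing chain
#'
#' Applies, in order: fingerprint cropping, Savitzky-Golay smoothing, SNV,
#' baseline correction and mean centering, with optional replicate averaging
#' before or after the chain. The stages actually executed are recorded, in
#' order, in the `"provenance"` attribute of the result.
#'
#' @param ds a [spectral_dataset()].
#' @param config a [preprocess_config()].
#' @return the preprocessed `spectral_dataset` with attributes
#'   `"provenance"` (stage log) and `"config"`.
#' @export
preprocess <- function(ds, config = preprocess_config()) {
  if (!inherits(config, "preprocess_config")) {
    abort("config must come from preprocess_config()")
  }
  log <- character()
  step <- function(label) log <<- c(log, label)
  if (config$average == "before") {
    ds <- average_replicates(ds)
    step("average_replicates")
  }
  if (!is.null(config$crop)) {
    ds <- crop_fingerprint(ds, config$crop[1], config$crop[2])
    step(sprintf("crop[%g,%g]", config$crop[1], config$crop[2]))
  }
  if (config$savgol) {
    ds <- savgol_smooth(ds, config$savgol_window, config$savgol_polyorder)
    step(sprintf("savgol(window=%d,order=%d)",
                 config$savgol_window, config$savgol_polyorder))
  }
  if (config$snv) {
    ds <- snv_normalize(ds)
    step("snv")
  }
  if (config$baseline != "none") {
    ds <- baseline_correct(ds, config$baseline,
                           lambda = config$als_lambda, p = config$als_p)
    step(paste0("baseline(", config$baseline, ")"))
  }
  if (config$center) {
    ds <- mean_center(ds)
    step("mean_center")
  }
  if (config$average == "after") {
    ds <- average_replicates(ds)
    step("average_replicates")
  }
  attr(ds, "provenance") <- log
  attr(ds, "config") <- config
  ds
}
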
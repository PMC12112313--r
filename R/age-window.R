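#' Age windows
#'
#' An age window is a closed interval of hours since pupariation that is
#' compatible with some piece of evidence. Post-eclosion evidence (an empty
#' puparium) has no upper bound, represented as `Inf`. Every window carries
#' a provenance log naming the evidence it came from.
#'
#' @param lower_h,upper_h window bounds in hours; `upper_h` may be `Inf`.
#' @param provenance character vector describing the contributing evidence.
#' @return an `age_window` object.
#' @export
age_window <- function(lower_h, upper_h, provenance) {
  stopifnot(is.numeric(lower_h), is.numeric(upper_h),
            length(lower_h) == 1, length(upper_h) == 1)
  if (lower_h < 0) abort("age window lower bound must be >= 0 h")
  if (upper_h < lower_h) {
    abort(sprintf("age window bounds out of order: [%g, %g]",
                  lower_h, upper_h))
  }
  if (!length(provenance)) abort("age window requires provenance")
  structure(list(lower_h = as.numeric(lower_h),
                 upper_h = as.numeric(upper_h),
                 provenance = as.character(provenance)),
            class = "age_window")
}

#' @export
format.age_window <- function(x, ...) {
  up <- if (is.infinite(x$upper_h)) "open" else sprintf("%.1f", x$upper_h)
  sprintf("[%.1f, %s] h since pupariation", x$lower_h, up)
}

#' @export
print.age_window <- function(x, ...) {
  cat("<age_window>", format(x), "\n")
  cat("evidence:\n")
  cat(paste0("  - ", x$provenance, collapse = "\n"), "\n")
  invisible(x)
}

#' @param x an `age_window`.
#' @param ... unused.
#' @return `tidy()` returns a one-row tibble with the bounds, the window
#'   width and the number of evidence items.
#' @rdname age_window
#' @exportS3Method generics::tidy
#' @export
tidy.age_window <- function(x, ...) {
  tibble(lower_h = x$lower_h, upper_h = x$upper_h,
         width_h = x$upper_h - x$lower_h,
         n_evidence = length(x$provenance))
}

# Intersection of two windows; NULL signals an empty intersection.
window_intersect <- function(a, b) {
  lo <- max(a$lower_h, b$lower_h)
  hi <- min(a$upper_h, b$upper_h)
  if (lo > hi) return(NULL)
  age_window(lo, hi, c(a$provenance, b$provenance))
}

# Convex hull (union fallback for conflicting evidence).
window_hull <- function(a, b) {
  age_window(min(a$lower_h, b$lower_h), max(a$upper_h, b$upper_h),
             c(a$provenance, b$provenance))
}
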
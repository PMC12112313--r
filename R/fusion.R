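#' Hour window implied by a spectral age class
#'
#' Spectral sampling is daily, so a predicted age class of day `d` places
#' the sample in the half-open daily bin `[24 d, 24 (d + 1))`, clipped at
#' eclosion (the total intra-puparial duration at that temperature). The
#' terminal `EMPTY_PUPARIUM` class means eclosion has happened, so the
#' window is `[total, Inf)` -- open above, because spectra cannot say how
#' long ago the adult left.
#'
#' @param day_class non-negative day index, or `"EMPTY_PUPARIUM"`.
#' @param temperature_C a table grid temperature.
#' @param tables staging tables; default the packaged ones.
#' @return an [age_window()].
#' @export
spectral_day_window <- function(day_class, temperature_C,
                                tables = load_staging_tables()) {
  total <- total_duration(tables, temperature_C)
  if (identical(as.character(day_class), "EMPTY_PUPARIUM")) {
    return(age_window(total, Inf, sprintf(
      "empty puparium at %g degC: post-eclosion, >= %g h",
      temperature_C, total)))
  }
  day <- suppressWarnings(as.numeric(day_class))
  if (is.na(day) || day < 0 || day != floor(day)) {
    abort("day_class must be a non-negative integer or \"EMPTY_PUPARIUM\"",
          class = "pupage_domain_error")
  }
  lo <- 24 * day
  if (lo > total) {
    abort(sprintf(
      "day class %d starts at %g h, beyond eclosion (%g h) at %g degC",
      day, lo, total, temperature_C), class = "pupage_domain_error")
  }
  age_window(lo, min(24 * (day + 1), total), sprintf(
    "spectral age class day %d at %g degC: daily bin clipped at %g h",
    day, temperature_C, total))
}

#' Fuse the morphological and spectral age windows
#'
#' The two evidence tracks are combined by interval intersection, narrowing
#' the PMI_min window to ages compatible with both. Disjoint windows are a
#' reported conflict -- both source windows are kept and flagged, never
#' silently merged -- because in casework each line of evidence must remain
#' visible.
#'
#' @param morph morphological [age_window()] (from [estimate_age()]).
#' @param spectral spectral [age_window()] (from [spectral_day_window()]).
#' @param temperature_C temperature the windows were computed at (metadata).
#' @return a `pmi_report` with both source windows, the fused window (or
#'   `NULL` on conflict), and a `conflict` flag.
#' @export
fuse_windows <- function(morph, spectral, temperature_C = NA_real_) {
  fused <- window_intersect(morph, spectral)
  structure(list(morphological_window = morph,
                 spectral_window = spectral,
                 fused_window = fused,
                 conflict = is.null(fused),
                 temperature_C = temperature_C),
            class = "pmi_report")
}

#' @export
print.pmi_report <- function(x, ...) {
  cat("<pmi_report>\n")
  cat("  morphological:", format(x$morphological_window), "\n")
  cat("  spectral:     ", format(x$spectral_window), "\n")
  if (x$conflict) {
    cat("  CONFLICT: the two windows are disjoint; no fused estimate\n")
  } else {
    cat("  fused:        ", format(x$fused_window), "\n")
  }
  invisible(x)
}

#' @param x a `pmi_report`.
#' @param ... unused.
#' @return `tidy()` returns one row per window (morphological, spectral,
#'   fused) with bounds and the conflict flag.
#' @rdname fuse_windows
#' @exportS3Method generics::tidy
#' @export
tidy.pmi_report <- function(x, ...) {
  rows <- list(
    mutate(tidy(x$morphological_window), evidence = "morphological"),
    mutate(tidy(x$spectral_window), evidence = "spectral"))
  if (!x$conflict) {
    rows <- c(rows, list(mutate(tidy(x$fused_window), evidence = "fused")))
  }
  mutate(bind_rows(rows), conflict = x$conflict,
         temperature_C = x$temperature_C)
}

#' Plot a PMI report's windows
#'
#' @param object a `pmi_report`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.pmi_report <- function(object, ...) {
  df <- tidy(object)
  df$evidence <- factor(df$evidence,
                        levels = rev(c("morphological", "spectral", "fused")))
  upper <- ifelse(is.infinite(df$upper_h),
                  max(df$lower_h) * 1.25 + 24, df$upper_h)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$lower_h, xend = upper, y = .data$evidence,
      yend = .data$evidence, colour = .data$evidence), linewidth = 3) +
    ggplot2::labs(x = "Hours since pupariation", y = NULL) +
    ggplot2::guides(colour = "none")
}

# JSON-serializable view used by the command-line interface.
pmi_report_list <- function(x) {
  win <- function(w) if (is.null(w)) NULL else
    list(lower_h = w$lower_h,
         upper_h = if (is.infinite(w$upper_h)) "open" else w$upper_h,
         provenance = w$provenance)
  list(temperature_C = x$temperature_C,
       morphological_window = win(x$morphological_window),
       spectral_window = win(x$spectral_window),
       fused_window = win(x$fused_window),
       conflict = x$conflict)
}
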
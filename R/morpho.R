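#' Age window for one organ sub-stage at a grid temperature
#'
#' Looks up the packaged duration tables: the window for observing organ
#' `organ` in sub-stage `sub_stage` at constant temperature `temperature_C`
#' is `[h_min, h_max]` hours since pupariation. Because observations during
#' the timing study were made every 8 h, the printed bounds are treated as
#' conservative: the true onset/offset lies within one sampling interval of
#' them.
#'
#' @param tables a `staging_tables` tibble from [load_staging_tables()].
#' @param organ one of [pup_organs()].
#' @param sub_stage a sub-stage label valid for `organ`
#'   (see [pup_sub_stages()]); `"ABSENT"` means the organ is not yet visible
#'   and is only available for organs whose tables time that state.
#' @param temperature_C one of the grid temperatures [pup_temperatures()].
#' @param widen_by_sd if `TRUE`, extend the window by the printed standard
#'   deviations (`lower - sd_min`, floored at 0, and `upper + sd_max`).
#'   Off by default: the tables' bare min/max are the primary estimate and
#'   the SDs describe replicate scatter.
#' @return an [age_window()].
#' @export
#' @examples
#' tables <- load_staging_tables()
#' stage_window(tables, "compound_eyes", "IV", 25)
stage_window <- function(tables, organ, sub_stage, temperature_C,
                         widen_by_sd = FALSE) {
  organ <- match.arg(organ, pup_organs())
  if (!temperature_C %in% pup_temperatures()) {
    abort(sprintf(
      "temperature %g degC is off the table grid; use interpolate_window()",
      temperature_C), class = "pupage_domain_error")
  }
  if (!sub_stage %in% pup_sub_stages(organ)) {
    abort(sprintf("sub-stage '%s' is not defined for %s (valid: %s)",
                  sub_stage, organ,
                  paste(pup_sub_stages(organ), collapse = ", ")),
          class = "pupage_domain_error")
  }
  rec <- tables[tables$organ == organ &
                  tables$temperature_C == temperature_C &
                  tables$sub_stage == sub_stage, ]
  if (nrow(rec) != 1) {
    abort(sprintf("no record for (%s, %s, %g degC)",
                  organ, sub_stage, temperature_C),
          class = "pupage_domain_error")
  }
  if (rec$absent) {
    abort(sprintf(
      "sub-stage %s of %s was never observed at %g degC ('-' in the table)",
      sub_stage, organ, temperature_C), class = "pupage_stage_absent")
  }
  lo <- rec$h_min
  hi <- rec$h_max
  prov <- sprintf("%s %s at %g degC: table window [%g, %g] h",
                  organ, sub_stage, temperature_C, lo, hi)
  if (widen_by_sd) {
    lo <- max(0, lo - rec$sd_min)
    hi <- hi + rec$sd_max
    prov <- paste0(prov, sprintf(" widened by SD (-%g/+%g)",
                                 rec$sd_min, rec$sd_max))
  }
  age_window(lo, hi, prov)
}

#' Age window at an off-grid temperature by linear interpolation
#'
#' The timing study used six constant temperatures; between adjacent grid
#' points `h_min` and `h_max` (and, when requested, the SDs) are
#' interpolated linearly in temperature. This is deliberately the minimal
#' assumption -- no thermal-summation model is implied -- and the provenance
#' records that the window is interpolated. Development fails at 16 degrees
#' C, so no extrapolation outside [19, 34] is permitted.
#'
#' @inheritParams stage_window
#' @param temperature_C any temperature in [19, 34] degrees C.
#' @return an [age_window()]; exactly the table window when `temperature_C`
#'   is on the grid.
#' @export
interpolate_window <- function(tables, organ, sub_stage, temperature_C,
                               widen_by_sd = FALSE) {
  grid <- pup_temperatures()
  if (temperature_C < min(grid) || temperature_C > max(grid)) {
    abort(sprintf(
      paste0("temperature %g degC is outside [%d, %d]; development is not ",
             "viable below the grid and no extrapolation is offered"),
      temperature_C, min(grid), max(grid)),
      class = "pupage_extrapolation_error")
  }
  if (temperature_C %in% grid) {
    return(stage_window(tables, organ, sub_stage, temperature_C,
                        widen_by_sd = widen_by_sd))
  }
  t_lo <- max(grid[grid < temperature_C])
  t_hi <- min(grid[grid > temperature_C])
  w_lo <- stage_window_record(tables, organ, sub_stage, t_lo)
  w_hi <- stage_window_record(tables, organ, sub_stage, t_hi)
  frac <- (temperature_C - t_lo) / (t_hi - t_lo)
  lerp <- function(a, b) a + frac * (b - a)
  lo <- lerp(w_lo$h_min, w_hi$h_min)
  hi <- lerp(w_lo$h_max, w_hi$h_max)
  prov <- sprintf(
    "%s %s at %g degC: linear interpolation between %d and %d degC -> [%g, %g] h",
    organ, sub_stage, temperature_C, t_lo, t_hi, lo, hi)
  if (widen_by_sd) {
    lo <- max(0, lo - lerp(w_lo$sd_min, w_hi$sd_min))
    hi <- hi + lerp(w_lo$sd_max, w_hi$sd_max)
    prov <- paste0(prov, " widened by interpolated SD")
  }
  age_window(lo, hi, prov)
}

# Fetch one record, insisting it exists and is non-absent (interpolation
# needs real times on both flanks).
stage_window_record <- function(tables, organ, sub_stage, temperature_C) {
  organ <- match.arg(organ, pup_organs())
  if (!sub_stage %in% pup_sub_stages(organ)) {
    abort(sprintf("sub-stage '%s' is not defined for %s", sub_stage, organ),
          class = "pupage_domain_error")
  }
  rec <- tables[tables$organ == organ &
                  tables$temperature_C == temperature_C &
                  tables$sub_stage == sub_stage, ]
  if (nrow(rec) != 1 || rec$absent) {
    abort(sprintf(
      "cannot interpolate: flanking record (%s, %s, %g degC) is absent",
      organ, sub_stage, temperature_C), class = "pupage_stage_absent")
  }
  rec
}

#' Estimate intra-puparial age from a set of organ observations
#'
#' Each observed (organ, sub-stage) pair constrains the age to that
#' sub-stage's table window; the joint estimate is the intersection of all
#' windows. Adding observations can only narrow the window. Observations
#' whose windows do not overlap are mutually incompatible -- by default this
#' raises a conflict error naming the offending pair, because in casework an
#' impossible combination means a staging error that must be resolved, not
#' averaged away. With `union = TRUE` the convex hull is returned instead,
#' with a warning.
#'
#' @inheritParams stage_window
#' @param observations a data frame with columns `organ` and `sub_stage`,
#'   one row per observed organ.
#' @param temperature_C rearing/scene temperature; interpolated linearly if
#'   off the table grid.
#' @param union return the convex hull (with a warning) instead of erroring
#'   when windows conflict.
#' @return an [age_window()] whose provenance lists every observation.
#' @export
#' @examples
#' tables <- load_staging_tables()
#' obs <- tibble::tibble(organ = c("compound_eyes", "abdomen"),
#'                       sub_stage = c("IV", "IV"))
#' estimate_age(tables, obs, temperature_C = 25)
estimate_age <- function(tables, observations, temperature_C,
                         widen_by_sd = FALSE, union = FALSE) {
  if (!is.data.frame(observations) ||
      !all(c("organ", "sub_stage") %in% names(observations))) {
    abort("observations must be a data frame with columns organ, sub_stage",
          class = "pupage_domain_error")
  }
  if (nrow(observations) < 1) {
    abort("at least one observation is required",
          class = "pupage_domain_error")
  }
  windows <- purrr::pmap(
    list(observations$organ, observations$sub_stage),
    function(org, st) {
      interpolate_window(tables, org, st, temperature_C,
                         widen_by_sd = widen_by_sd)
    })
  acc <- windows[[1]]
  for (i in seq_along(windows)[-1]) {
    nxt <- window_intersect(acc, windows[[i]])
    if (is.null(nxt)) {
      offender <- conflicting_pairs(windows, observations)
      if (union) {
        warn(paste0("conflicting observations (", offender,
                    "); returning the convex hull of all windows"))
        acc <- Reduce(window_hull, windows)
        return(acc)
      }
      abort(paste0("observations are mutually incompatible: ", offender),
            class = "pupage_conflict_error")
    }
    acc <- nxt
  }
  acc
}

# Name every pairwise-disjoint pair of observation windows.
conflicting_pairs <- function(windows, observations) {
  lab <- paste(observations$organ, observations$sub_stage)
  bad <- character()
  for (i in seq_along(windows)) {
    for (j in seq_along(windows)[-seq_len(i)]) {
      if (is.null(window_intersect(windows[[i]], windows[[j]]))) {
        bad <- c(bad, sprintf("{%s} vs {%s}", lab[i], lab[j]))
      }
    }
  }
  paste(bad, collapse = "; ")
}

#' Total intra-puparial duration at a temperature
#'
#' The development time from pupariation to eclosion, taken as the maximum
#' over the seven organ systems of the terminal sub-stage's latest
#' observation (`h_max`). On the packaged tables all organs agree on this
#' terminal time at every grid temperature (192 h at 19 degrees C down to
#' 77.3 h at 34 degrees C).
#'
#' @inheritParams stage_window
#' @param temperature_C temperature in [19, 34] degrees C; linear
#'   interpolation between grid totals when off-grid.
#' @return total duration in hours.
#' @export
total_duration <- function(tables, temperature_C) {
  grid <- pup_temperatures()
  if (temperature_C < min(grid) || temperature_C > max(grid)) {
    abort(sprintf("temperature %g degC is outside [%d, %d]",
                  temperature_C, min(grid), max(grid)),
          class = "pupage_extrapolation_error")
  }
  total_at <- function(tc) {
    per_organ <- vapply(pup_organs(), function(org) {
      ser <- tables[tables$organ == org & tables$temperature_C == tc &
                      !tables$absent, ]
      ser <- ser[match(pup_sub_stages(org), ser$sub_stage), ]
      ser <- ser[!is.na(ser$h_max), ]
      ser$h_max[nrow(ser)]
    }, numeric(1))
    max(per_organ)
  }
  if (temperature_C %in% grid) return(total_at(temperature_C))
  t_lo <- max(grid[grid < temperature_C])
  t_hi <- min(grid[grid > temperature_C])
  frac <- (temperature_C - t_lo) / (t_hi - t_lo)
  total_at(t_lo) + frac * (total_at(t_hi) - total_at(t_lo))
}

#' Read a field-observation file
#'
#' @param path CSV with columns `organ,sub_stage`, one row per observed
#'   organ.
#' @return a tibble suitable for [estimate_age()].
#' @export
read_observations <- function(path) {
  obs <- readr::read_csv(path, col_types = readr::cols(
    organ = readr::col_character(),
    sub_stage = readr::col_character()), progress = FALSE)
  bad <- setdiff(obs$organ, pup_organs())
  if (length(bad)) {
    abort(paste0("unknown organ(s) in observation file: ",
                 paste(bad, collapse = ", ")),
          class = "pupage_domain_error")
  }
  obs
}
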
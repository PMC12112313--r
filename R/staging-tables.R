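#' Organ systems and sub-stage labels used by the staging tables
#'
#' Intra-puparial development is scored on seven organ systems. Compound eyes
#' and abdomen are divided into six sub-stages (I--VI), thorax and mouthparts
#' into seven (I--VII), and antennae, wings and legs into eight (I--VIII).
#' For mouthparts, antennae, wings and legs the tables additionally print an
#' "organ not yet visible" column, carried here as the pseudo-sub-stage
#' `ABSENT` because it is a legitimate field observation with its own
#' duration window.
#'
#' @return `pup_organs()` returns the seven organ names; `pup_sub_stages()`
#'   the valid sub-stage labels for one organ, in developmental order.
#' @export
pup_organs <- function() {
  c("compound_eyes", "abdomen", "thorax", "mouthparts",
    "antennae", "wings", "legs")
}

#' @param organ one of `pup_organs()`.
#' @rdname pup_organs
#' @export
pup_sub_stages <- function(organ) {
  organ <- match.arg(organ, pup_organs())
  n <- c(compound_eyes = 6, abdomen = 6, thorax = 7, mouthparts = 7,
         antennae = 8, wings = 8, legs = 8)[[organ]]
  pre <- if (organ %in% c("compound_eyes", "abdomen", "thorax")) {
    character()
  } else {
    "ABSENT"
  }
  c(pre, c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")[seq_len(n)])
}

#' Grid of rearing temperatures covered by the duration tables
#'
#' @return integer vector of the six constant temperatures (degrees C) at
#'   which intra-puparial development was timed. Development fails below
#'   this range (16 degrees C), so no extrapolation is offered.
#' @export
pup_temperatures <- function() {
  c(19L, 22L, 25L, 28L, 31L, 34L)
}

# Descriptive whole-body scheme. The 12 whole-body sub-stages (A-L:
# pre-pupa, early/late cryptocephalic pupa, phanerocephalic pupa, pharate
# adult I-VIII) are carried as documentation only; their per-temperature
# durations are not part of the packaged numeric data.
whole_body_scheme_notes <- function() {
  paste(
    "Whole-body intra-puparial development comprises 12 qualitative",
    "sub-stages A-L: A pre-pupa; B early cryptocephalic pupa; C late",
    "cryptocephalic pupa; D phanerocephalic pupa; E-L pharate adult stages",
    "I-VIII, scored on colouration of compound eyes, legs, wings, antennae",
    "and mouthparts. Only the organ-level tables are quantitative."
  )
}

#' Load the packaged intra-puparial duration tables
#'
#' Reads the minimum/maximum duration tables for the seven organ systems at
#' the six rearing temperatures. Each row gives, for one (organ,
#' temperature, sub-stage) combination, the earliest (`h_min`) and latest
#' (`h_max`) hour after pupariation at which that sub-stage was recorded,
#' with their standard deviations across replicates. Cells printed as "-"
#' (sub-stage never observed at that temperature) are loaded as missing
#' values with `absent = TRUE`, never as zero.
#'
#' @param path path to a duration table CSV with columns
#'   `organ,temperature_C,sub_stage,h_min,sd_min,h_max,sd_max,absent`.
#'   Defaults to the table packaged with pupage.
#' @return a `staging_tables` tibble (one row per record) with attributes
#'   `temperatures` (the grid) and `scheme_notes` (the qualitative
#'   whole-body A--L scheme).
#' @export
#' @examples
#' tables <- load_staging_tables()
#' dplyr::filter(tables, organ == "compound_eyes", temperature_C == 25)
load_staging_tables <- function(path = NULL) {
  path <- path %||% system.file("extdata", "staging_durations.csv",
                                package = "pupage", mustWork = TRUE)
  spec <- readr::cols(
    organ = readr::col_character(),
    temperature_C = readr::col_integer(),
    sub_stage = readr::col_character(),
    h_min = readr::col_double(),
    sd_min = readr::col_double(),
    h_max = readr::col_double(),
    sd_max = readr::col_double(),
    absent = readr::col_logical()
  )
  tbl <- readr::read_csv(path, col_types = spec, progress = FALSE)
  check_tables_complete(tbl)
  structure(
    tbl,
    temperatures = pup_temperatures(),
    scheme_notes = whole_body_scheme_notes(),
    class = c("staging_tables", class(tibble()))
  )
}

# Completeness: every (organ, temperature) series must be present with
# exactly the expected sub-stage labels, and absent cells must be flagged.
check_tables_complete <- function(tbl) {
  bad_organ <- setdiff(unique(tbl$organ), pup_organs())
  if (length(bad_organ)) {
    abort(paste0("unknown organ in duration table: ",
                 paste(bad_organ, collapse = ", ")))
  }
  for (org in pup_organs()) {
    for (tc in pup_temperatures()) {
      have <- tbl$sub_stage[tbl$organ == org & tbl$temperature_C == tc]
      want <- pup_sub_stages(org)
      if (!setequal(have, want) || anyDuplicated(have)) {
        abort(sprintf(
          "duration table incomplete for (%s, %d degC): have {%s}, need {%s}",
          org, tc, paste(have, collapse = ","), paste(want, collapse = ",")))
      }
    }
  }
  with_times <- !tbl$absent
  if (anyNA(tbl$h_min[with_times]) || anyNA(tbl$h_max[with_times])) {
    off <- tbl[with_times & (is.na(tbl$h_min) | is.na(tbl$h_max)), ]
    abort(sprintf("missing duration for non-absent record (%s, %d degC, %s)",
                  off$organ[1], off$temperature_C[1], off$sub_stage[1]))
  }
  if (any(!is.na(tbl$h_min[tbl$absent]))) {
    abort("absent records must not carry durations")
  }
  invisible(tbl)
}

#' Integrity report for a staging table
#'
#' Screens a duration table for (a) records whose `h_min` exceeds `h_max`,
#' (b) series in which `h_min` or `h_max` decreases between consecutive
#' sub-stages of the same organ and temperature, and (c) absent cells in the
#' middle of a series. The packaged tables are preserved verbatim from the
#' source measurements, so the printed anomalies (notably the antennae
#' series) are reported here rather than silently corrected.
#'
#' @param tables a `staging_tables` tibble from [load_staging_tables()].
#' @return a tibble of flags with columns `type` (one of
#'   `"min_exceeds_max"`, `"nonmonotone"`, `"absent_mid_series"`), `organ`,
#'   `temperature_C`, `sub_stage`, `field`, and a human-readable `detail`.
#'   Zero rows means a clean table. Never modifies its input.
#' @export
validate_staging_tables <- function(tables) {
  flags <- list()
  add <- function(type, organ, tc, stage, field, detail) {
    flags[[length(flags) + 1]] <<- tibble(
      type = type, organ = organ, temperature_C = tc,
      sub_stage = stage, field = field, detail = detail)
  }

  rec <- tables[!tables$absent & tables$h_min > tables$h_max, ]
  for (i in seq_len(nrow(rec))) {
    add("min_exceeds_max", rec$organ[i], rec$temperature_C[i],
        rec$sub_stage[i], "h_min/h_max",
        sprintf("h_min %.1f > h_max %.1f", rec$h_min[i], rec$h_max[i]))
  }

  for (org in unique(tables$organ)) {
    stages <- pup_sub_stages(org)
    for (tc in unique(tables$temperature_C)) {
      ser <- tables[tables$organ == org & tables$temperature_C == tc, ]
      ser <- ser[match(stages, ser$sub_stage), ]
      pres <- which(!ser$absent)
      if (length(pres) && any(ser$absent[seq(min(pres), max(pres))])) {
        mid <- intersect(which(ser$absent), seq(min(pres), max(pres)))
        for (i in mid) {
          add("absent_mid_series", org, tc, ser$sub_stage[i], NA_character_,
              "absent cell between observed sub-stages")
        }
      }
      for (field in c("h_min", "h_max")) {
        v <- ser[[field]][pres]
        drop <- which(diff(v) < 0)
        for (d in drop) {
          add("nonmonotone", org, tc, ser$sub_stage[pres[d + 1]], field,
              sprintf("%s falls from %.1f (%s) to %.1f (%s)", field,
                      v[d], ser$sub_stage[pres[d]],
                      v[d + 1], ser$sub_stage[pres[d + 1]]))
        }
      }
    }
  }

  if (length(flags)) bind_rows(flags) else tibble(
    type = character(), organ = character(), temperature_C = integer(),
    sub_stage = character(), field = character(), detail = character())
}
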
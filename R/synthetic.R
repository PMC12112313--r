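#' Default band model for synthetic puparium spectra
#'
#' A parametric description of the fingerprint-region absorption bands seen
#' on blow-fly puparia, used by the spectrum generator. Each band is a
#' Gaussian with a centre, width (sigma), baseline amplitude at pupariation,
#' a signed fractional amplitude change per unit development (`age_slope`;
#' the 1395 cm-1 free-amino-acid/lipid band decays with age, the protein
#' amide bands grow mildly), and a fractional amplitude shift for the
#' post-eclosion empty puparium (`empty_shift`; protein bands collapse once
#' the pharate adult has left, carbohydrate/chitin bands of the cuticle
#' persist or dominate). Slope magnitudes are conventions chosen for
#' realistic class overlap, not measured quantities; both slopes scale with
#' the generator's `effect_size`.
#'
#' @return a tibble of band parameters with one row per band.
#' @export
default_band_model <- function() {
  tibble(
    center_cm1 = c(1632, 1516, 1395, 1240, 1080, 1030),
    width_cm1 = c(25, 20, 18, 22, 25, 20),
    base_amplitude = c(1.00, 0.75, 0.60, 0.45, 0.40, 0.50),
    age_slope = c(0.30, 0.25, -0.60, 0.15, 0.10, 0.05),
    empty_shift = c(-0.50, -0.45, -0.70, -0.30, 0.20, 0.30),
    label = c("amide I (C=O stretch)",
              "amide II (N-H bend / C-N stretch)",
              "COO- of free fatty acids, amino acids and peptides",
              "amide III / C-O stretch",
              "PO2- symmetric stretch / C-O",
              "C-O(H) carbohydrate"))
}

#' Synthetic-spectra generator configuration
#'
#' Defaults reproduce the acquisition design of the spectroscopy protocol:
#' five replicate spectra per 24-h time point from pupariation to eclosion
#' at one of 19, 25 or 31 degrees C, plus five terminal empty-puparium
#' spectra, on a 1800 -> 900 cm-1 grid at 4 cm-1 resolution.
#'
#' @param temperature_C rearing temperature (one of 19, 25, 31 by design;
#'   any table grid temperature is accepted).
#' @param timepoint_interval_h sampling interval in hours.
#' @param n_replicates spectra per time point.
#' @param include_empty_puparium add the terminal post-eclosion class?
#' @param effect_size multiplier (>= 0) on all age slopes and on the
#'   empty-puparium shift; 0 makes every class-conditional mean identical.
#' @param noise_sd i.i.d. Gaussian noise, absorbance units.
#' @param baseline_drift half-range of the per-spectrum linear baseline
#'   slope (absorbance units per cm-1), drawn uniformly.
#' @param seed RNG seed for the whole dataset draw.
#' @param bands band model tibble, see [default_band_model()].
#' @param wavenumbers wavenumber grid (descending by convention).
#' @return a `generator_config` list.
#' @export
generator_config <- function(temperature_C = 25, timepoint_interval_h = 24,
                             n_replicates = 5,
                             include_empty_puparium = TRUE,
                             effect_size = 1, noise_sd = 0.01,
                             baseline_drift = 1e-4, seed = 1,
                             bands = default_band_model(),
                             wavenumbers = seq(1800, 900, by = -4)) {
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  if (effect_size < 0) abort("effect_size must be >= 0")
  structure(list(temperature_C = temperature_C,
                 timepoint_interval_h = timepoint_interval_h,
                 n_replicates = n_replicates,
                 include_empty_puparium = include_empty_puparium,
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_drift = baseline_drift, seed = seed,
                 bands = bands, wavenumbers = wavenumbers),
            class = "generator_config")
}

# Noise-free forward model: sum of Gaussian bands with age- (or empty-)
# adjusted amplitudes.
band_profile <- function(bands, development_fraction, effect_size,
                         wavenumbers) {
  amp <- if (identical(development_fraction, "EMPTY")) {
    bands$base_amplitude * (1 + effect_size * bands$empty_shift)
  } else {
    bands$base_amplitude *
      (1 + effect_size * bands$age_slope * development_fraction)
  }
  terms <- vapply(seq_len(nrow(bands)), function(i) {
    amp[i] * exp(-(wavenumbers - bands$center_cm1[i])^2 /
                   (2 * bands$width_cm1[i]^2))
  }, numeric(length(wavenumbers)))
  rowSums(matrix(terms, nrow = length(wavenumbers)))
}

#' Simulate one puparium spectrum
#'
#' Absorbance is the sum of the Gaussian bands (amplitudes adjusted for the
#' development fraction, or for the empty-puparium profile), a linear
#' baseline drift, and i.i.d. Gaussian noise. With zero noise and drift the
#' result equals the analytic Gaussian sum exactly.
#'
#' @param bands band model tibble ([default_band_model()]).
#' @param development_fraction number in \[0, 1\] (0 = pupariation, 1 =
#'   eclosion) or the string `"EMPTY"` for an empty puparium.
#' @param effect_size multiplier on the age slopes.
#' @param noise_sd Gaussian noise SD in absorbance units.
#' @param drift_slope linear baseline slope (absorbance per cm-1), applied
#'   around the grid midpoint.
#' @param wavenumbers wavenumber grid.
#' @param seed optional seed for the noise draw.
#' @return numeric absorbance vector along `wavenumbers`.
#' @export
simulate_spectrum <- function(bands = default_band_model(),
                              development_fraction = 0, effect_size = 1,
                              noise_sd = 0, drift_slope = 0,
                              wavenumbers = seq(1800, 900, by = -4),
                              seed = NULL) {
  if (!identical(development_fraction, "EMPTY")) {
    if (!is.numeric(development_fraction) ||
        development_fraction < 0 || development_fraction > 1) {
      abort("development_fraction must lie in [0, 1] or be \"EMPTY\"")
    }
  }
  y <- band_profile(bands, development_fraction, effect_size, wavenumbers) +
    drift_slope * (wavenumbers - mean(wavenumbers))
  draw <- function() y + rnorm(length(wavenumbers), sd = noise_sd)
  if (noise_sd == 0) return(y)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a full spectral dataset for one temperature
#'
#' Generates `n_replicates` spectra per age class. Age classes are the day
#' indices `0, 1, ...` whose sampling time `24 * day` falls before eclosion
#' at the configured temperature (total intra-puparial duration from the
#' packaged staging tables), with `development_fraction = 24 * day / total`,
#' plus the terminal `EMPTY_PUPARIUM` class when enabled. The whole draw is
#' reproducible from `config$seed`.
#'
#' @param config a [generator_config()].
#' @param tables staging tables used for the total duration; defaults to
#'   the packaged tables.
#' @return a [spectral_dataset()].
#' @export
simulate_dataset <- function(config = generator_config(),
                             tables = load_staging_tables()) {
  total <- total_duration(tables, config$temperature_C)
  days <- 0:ceiling(total / config$timepoint_interval_h)
  days <- days[days * config$timepoint_interval_h < total]
  classes <- as.character(days)
  fractions <- as.list(days * config$timepoint_interval_h / total)
  if (config$include_empty_puparium) {
    classes <- c(classes, "EMPTY_PUPARIUM")
    fractions <- c(fractions, list("EMPTY"))
  }
  wn <- config$wavenumbers
  cols <- list()
  meta <- list()
  withr::with_seed(config$seed, {
    for (i in seq_along(classes)) {
      for (rep_i in seq_len(config$n_replicates)) {
        drift <- runif(1, -config$baseline_drift, config$baseline_drift)
        spec <- simulate_spectrum(
          bands = config$bands, development_fraction = fractions[[i]],
          effect_size = config$effect_size, noise_sd = config$noise_sd,
          drift_slope = drift, wavenumbers = wn)
        id <- sprintf("T%g_c%s_r%d", config$temperature_C, classes[i], rep_i)
        cols[[id]] <- spec
        meta[[id]] <- tibble(sample_id = id,
                             temperature_C = config$temperature_C,
                             age_class = classes[i], replicate = rep_i)
      }
    }
  })
  spectral_dataset(wn, do.call(cbind, cols), bind_rows(meta))
}
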
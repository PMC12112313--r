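# Shared builders for the test suite. All fixtures are built in code.

pkg_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_staging_tables()
    cache
  }
})

# Minimal spectral dataset from a plain matrix (wavenumbers x samples).
toy_dataset <- function(absorbance, wavenumbers = NULL, classes = NULL,
                        temperature = 25) {
  absorbance <- as.matrix(absorbance)
  n <- ncol(absorbance)
  wavenumbers <- wavenumbers %||% seq(1800, by = -4, length.out = nrow(absorbance))
  classes <- classes %||% rep("0", n)
  meta <- tibble::tibble(sample_id = paste0("s", seq_len(n)),
                         temperature_C = temperature,
                         age_class = as.character(classes),
                         replicate = seq_len(n))
  colnames(absorbance) <- meta$sample_id
  spectral_dataset(wavenumbers, absorbance, meta)
}

# Two well-separated Gaussian classes in feature space (delta-mu = 6 sigma).
separable_classes <- function(n_per_class = 20, p = 4, delta = 6, seed = 42) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * p), n_per_class),
               matrix(rnorm(n_per_class * p, mean = delta), n_per_class))
  })
  colnames(x) <- paste0("V", seq_len(p))
  list(x = x, y = factor(rep(c("a", "b"), each = n_per_class)))
}

expect_window <- function(w, lower, upper, tol = 1e-9) {
  expect_s3_class(w, "age_window")
  expect_equal(w$lower_h, lower, tolerance = tol)
  expect_equal(w$upper_h, upper, tolerance = tol)
}

`%||%` <- rlang::`%||%`
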
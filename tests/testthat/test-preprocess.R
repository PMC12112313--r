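test_that("fingerprint cropping keeps exactly the closed interval", {
  grid <- seq(4000, 600, by = -4)
  ds <- toy_dataset(matrix(rnorm(2 * length(grid)), ncol = 2),
                    wavenumbers = grid)
  cropped <- crop_fingerprint(ds)
  expect_equal(length(cropped$wavenumbers), (1800 - 900) / 4 + 1)   # 226
  expect_true(all(cropped$wavenumbers >= 900 & cropped$wavenumbers <= 1800))
  expect_identical(as.data.frame(cropped$metadata),
                   as.data.frame(ds$metadata))

  inside <- toy_dataset(matrix(rnorm(20), 10),
                        wavenumbers = seq(1700, 1000, length.out = 10))
  expect_identical(crop_fingerprint(inside)$absorbance, inside$absorbance)
  expect_error(crop_fingerprint(ds, lo = 1800, hi = 900), "lo > hi")
  expect_error(crop_fingerprint(ds, lo = 100, hi = 200), "no grid points")
})

test_that("Savitzky-Golay weights match the least-squares oracle", {
  # independent oracle: centre value of the quadratic least-squares fit
  # over offsets -2..2 -> weights (-3, 12, 17, 12, -3)/35
  A <- outer(-2:2, 0:2, "^")
  oracle <- (solve(t(A) %*% A) %*% t(A))[1, ]
  expect_equal(oracle, c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12)
  expect_equal(pupage:::savgol_kernel(5, 2), unname(oracle),
               tolerance = 1e-12)
})

test_that("Savitzky-Golay smoothing reproduces polynomials and constants", {
  x <- 1:30
  quad <- 0.5 * x^2 - 3 * x + 7
  sm <- savgol_smooth(quad, window = 5, polyorder = 2)
  interior <- 3:28
  expect_equal(sm[interior], quad[interior], tolerance = 1e-10)
  expect_equal(savgol_smooth(rep(4.2, 20)), rep(4.2, 20))
  expect_error(savgol_smooth(quad, window = 4), "odd")
  expect_error(savgol_smooth(quad, window = 3, polyorder = 3), "exceed")
})

test_that("cropping commutes with smoothing away from the window edges", {
  grid <- seq(2000, 600, by = -4)
  y <- sin(grid / 50) + 0.001 * grid
  ds <- toy_dataset(matrix(y, ncol = 1), wavenumbers = grid)
  smooth_then_crop <- crop_fingerprint(savgol_smooth(ds))
  crop_then_smooth <- savgol_smooth(crop_fingerprint(ds))
  n <- length(smooth_then_crop$wavenumbers)
  interior <- 3:(n - 2)
  expect_equal(smooth_then_crop$absorbance[interior, 1],
               crop_then_smooth$absorbance[interior, 1], tolerance = 1e-12)
})

test_that("SNV yields mean zero, unit sample SD, and affine invariance", {
  expect_equal(snv_normalize(c(1, 2, 3)), c(-1, 0, 1))
  for (s in 1:5) {
    v <- withr::with_seed(s, rnorm(50, mean = 3, sd = 2))
    z <- snv_normalize(v)
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
    a <- withr::with_seed(s + 100, runif(1, 0.5, 4))
    b <- withr::with_seed(s + 200, rnorm(1, sd = 10))
    expect_equal(snv_normalize(a * v + b), z, tolerance = 1e-9)
  }
  expect_error(snv_normalize(rep(1, 10)), "constant")
})

test_that("endpoint baseline correction removes lines and keeps peak heights", {
  grid <- seq(1800, 900, by = -4)
  line <- 0.002 * grid + 1
  expect_equal(baseline_correct(line), rep(0, length(grid)))

  peak <- exp(-(grid - 1400)^2 / (2 * 30^2))
  expect_equal(baseline_correct(peak)[c(1, length(grid))], c(0, 0))
  # peak injected on a slope is recovered at its injected height
  corrected <- baseline_correct(line + 0.8 * peak)
  expect_equal(max(corrected), 0.8, tolerance = 1e-6)

  # zero-ended spectra are (endpoints aside) unchanged
  expect_equal(baseline_correct(peak), peak - peak[1] -
                 (peak[length(grid)] - peak[1]) *
                 (seq_along(grid) - 1) / (length(grid) - 1))
  expect_error(baseline_correct(peak, method = "quadratic"))
})

test_that("ALS baseline tracks a curved background under a peak", {
  grid <- seq(1800, 900, by = -4)
  bg <- 1e-6 * (grid - 1350)^2 + 0.1
  peak <- 0.7 * exp(-(grid - 1400)^2 / (2 * 15^2))
  corrected <- baseline_correct(bg + peak, method = "als", lambda = 1e4)
  expect_equal(max(corrected), 0.7, tolerance = 0.05)
  expect_lt(mean(abs(corrected[abs(grid - 1400) > 100])), 0.02)
})

test_that("mean centering zeroes every wavenumber across samples", {
  m <- matrix(rnorm(60), nrow = 10)
  ds <- mean_center(toy_dataset(m))
  expect_lt(max(abs(rowMeans(ds$absorbance))), 1e-10)
  twice <- mean_center(ds)
  expect_equal(twice$absorbance, ds$absorbance)
  same <- toy_dataset(cbind(1:10, 1:10))
  expect_equal(mean_center(same)$absorbance,
               matrix(0, 10, 2), ignore_attr = TRUE)
  expect_error(mean_center(toy_dataset(matrix(1:10))), ">= 2 samples")
})

test_that("replicate averaging collapses groups to pointwise means", {
  m <- cbind(rep(0, 5), rep(2, 5), rep(1, 5), rep(3, 5))
  ds <- toy_dataset(m, classes = c("0", "0", "1", "1"))
  avg <- average_replicates(ds)
  expect_equal(n_samples(avg), 2)
  expect_equal(unname(avg$absorbance[, 1]), rep(1, 5))
  expect_equal(unname(avg$absorbance[, 2]), rep(2, 5))
  sizes <- attr(avg, "group_sizes")
  expect_equal(sizes$n, c(2L, 2L))

  five <- toy_dataset(matrix(rep(1:5, 5), nrow = 5), classes = rep("0", 5))
  one <- average_replicates(five)
  expect_equal(unname(one$absorbance[, 1]), 1:5)
})

test_that("the preprocessing chain runs in the documented order", {
  ds <- simulate_dataset(generator_config(temperature_C = 31, seed = 3))

  off <- preprocess(ds, preprocess_config(savgol = FALSE, snv = FALSE,
                                          baseline = "none", center = FALSE,
                                          average = "none"))
  expect_identical(off$absorbance, crop_fingerprint(ds)$absorbance)
  expect_equal(attr(off, "provenance"), "crop[900,1800]")

  prep <- preprocess(ds, preprocess_config(average = "none"))
  expect_equal(attr(prep, "provenance"),
               c("crop[900,1800]", "savgol(window=5,order=2)", "snv",
                 "baseline(linear_endpoints)", "mean_center"))
  expect_lt(max(abs(rowMeans(prep$absorbance))), 1e-10)

  # default averages replicates first: one spectrum per age class
  avg <- preprocess(ds, preprocess_config())
  expect_equal(n_samples(avg), length(unique(ds$metadata$age_class)))
  expect_equal(attr(avg, "provenance")[1], "average_replicates")

  # before centering, each spectrum carries unit SNV scale
  nocenter <- preprocess(ds, preprocess_config(center = FALSE,
                                               baseline = "none",
                                               average = "none"))
  sds <- apply(nocenter$absorbance, 2, sd)
  expect_equal(unname(sds), rep(1, n_samples(ds)), tolerance = 1e-12)
})

test_that("the pipeline is deterministic and affine-invariant in the raw data", {
  ds <- simulate_dataset(generator_config(temperature_C = 31, seed = 11))
  cfg <- preprocess_config(average = "none")
  once <- preprocess(ds, cfg)
  again <- preprocess(ds, cfg)
  expect_identical(once$absorbance, again$absorbance)

  for (s in 1:3) {
    gain <- withr::with_seed(s, runif(1, 0.5, 3))
    offset <- withr::with_seed(s + 50, rnorm(1))
    scaled <- ds
    scaled$absorbance <- gain * ds$absorbance + offset
    expect_equal(preprocess(scaled, cfg)$absorbance, once$absorbance,
                 tolerance = 1e-9)
  }
})
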
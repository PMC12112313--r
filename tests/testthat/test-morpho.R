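test_that("stage windows reproduce the published cells", {
  tables <- pkg_tables()
  expect_window(stage_window(tables, "compound_eyes", "IV", 25), 85.3, 93.3)
  expect_window(stage_window(tables, "wings", "I", 34), 8, 8)
  expect_window(stage_window(tables, "compound_eyes", "I", 19), 0, 29.3)
  # ABSENT is a usable pseudo-sub-stage where the tables time it
  expect_window(stage_window(tables, "antennae", "ABSENT", 25), 0, 26.7)
})

test_that("stage windows reject impossible queries", {
  tables <- pkg_tables()
  expect_error(stage_window(tables, "legs", "II", 34),
               class = "pupage_stage_absent")
  expect_error(stage_window(tables, "compound_eyes", "ABSENT", 25),
               class = "pupage_domain_error")
  expect_error(stage_window(tables, "compound_eyes", "VII", 25),
               class = "pupage_domain_error")
  expect_error(stage_window(tables, "compound_eyes", "IV", 23.5),
               class = "pupage_domain_error")
})

test_that("SD widening extends both bounds by the printed SDs", {
  tables <- pkg_tables()
  w <- stage_window(tables, "compound_eyes", "IV", 25, widen_by_sd = TRUE)
  expect_window(w, 85.3 - 4.6, 93.3 + 9.2)
  # lower bound floors at zero
  w0 <- stage_window(tables, "compound_eyes", "I", 19, widen_by_sd = TRUE)
  expect_equal(w0$lower_h, 0)
})

test_that("temperature interpolation is linear and exact on the grid", {
  tables <- pkg_tables()
  w <- interpolate_window(tables, "compound_eyes", "II", 23.5)
  expect_equal(w$lower_h, (32 + 24) / 2)        # midpoint of 22 and 25 degC
  expect_equal(w$upper_h, (37.3 + 24) / 2)
  for (org in c("compound_eyes", "thorax")) {
    exact <- stage_window(tables, org, "II", 25)
    interp <- interpolate_window(tables, org, "II", 25)
    expect_identical(tidy(interp)[1:2], tidy(exact)[1:2])
  }
  expect_error(interpolate_window(tables, "compound_eyes", "II", 16),
               class = "pupage_extrapolation_error")
  expect_error(interpolate_window(tables, "compound_eyes", "II", 35),
               class = "pupage_extrapolation_error")
  # legs II is absent at the 34 degC flank
  expect_error(interpolate_window(tables, "legs", "II", 32.5),
               class = "pupage_stage_absent")
})

test_that("estimate_age intersects observation windows", {
  tables <- pkg_tables()
  obs <- tibble::tibble(organ = c("compound_eyes", "abdomen"),
                        sub_stage = c("IV", "IV"))
  expect_window(estimate_age(tables, obs, 25), 88, 90.7)
  expect_window(estimate_age(tables, obs[1, ], 25), 85.3, 93.3)
  expect_error(
    estimate_age(tables,
                 tibble::tibble(organ = "compound_eyes",
                                sub_stage = c("I", "VI")), 19),
    class = "pupage_conflict_error")
  expect_warning(
    hull <- estimate_age(tables,
                         tibble::tibble(organ = "compound_eyes",
                                        sub_stage = c("I", "VI")), 19,
                         union = TRUE),
    "convex hull")
  expect_window(hull, 0, 192)
})

test_that("intersection narrows monotonically and ignores order", {
  tables <- pkg_tables()
  obs <- tibble::tibble(
    organ = c("compound_eyes", "abdomen", "thorax", "legs"),
    sub_stage = c("IV", "IV", "IV", "VI"))
  full <- estimate_age(tables, obs, 25)
  for (k in 1:3) {
    partial <- estimate_age(tables, obs[seq_len(k), ], 25)
    expect_gte(full$lower_h, partial$lower_h)
    expect_lte(full$upper_h, partial$upper_h)
    each <- estimate_age(tables, obs[k, ], 25)
    expect_gte(full$lower_h, each$lower_h)
    expect_lte(full$upper_h, each$upper_h)
  }
  for (s in 1:5) {
    perm <- withr::with_seed(s, obs[sample(nrow(obs)), ])
    shuffled <- estimate_age(tables, perm, 25)
    expect_equal(shuffled$lower_h, full$lower_h)
    expect_equal(shuffled$upper_h, full$upper_h)
  }
})

test_that("total duration matches the published range", {
  tables <- pkg_tables()
  expect_equal(total_duration(tables, 19), 192)
  expect_equal(total_duration(tables, 34), 77.3)
  expect_equal(total_duration(tables, 25), 117.3)
  # the total is the max over organs; no organ's terminal time exceeds it
  for (tc in pup_temperatures()) {
    terminals <- vapply(pup_organs(), function(org) {
      ser <- dplyr::filter(tables, organ == org, temperature_C == tc, !absent)
      ser$h_max[nrow(ser)]
    }, numeric(1))
    expect_equal(max(terminals), total_duration(tables, tc))
    expect_true(all(terminals <= total_duration(tables, tc)))
  }
  expect_equal(total_duration(tables, 20.5),
               (192 + 149.3) / 2)
  expect_error(total_duration(tables, 16),
               class = "pupage_extrapolation_error")
})

test_that("consecutive sub-stage windows cover development up to the 8-h sampling gap", {
  tables <- pkg_tables()
  for (org in setdiff(pup_organs(), "antennae")) {  # antennae: printed anomalies
    for (tc in pup_temperatures()) {
      ser <- dplyr::filter(tables, organ == org, temperature_C == tc, !absent)
      ser <- ser[match(pup_sub_stages(org), ser$sub_stage), ]
      ser <- ser[!is.na(ser$h_min), ]
      gaps <- ser$h_min[-1] - ser$h_max[-nrow(ser)]
      allowance <- 8 + ser$sd_max[-nrow(ser)] + ser$sd_min[-1] + 1e-9
      expect_true(all(gaps <= allowance),
                  label = sprintf("%s at %d degC gap coverage", org, tc))
      expect_equal(ser$h_min[1], 0)
      expect_lte(ser$h_max[nrow(ser)], total_duration(tables, tc))
    }
  }
})
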
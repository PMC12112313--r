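test_that("well-separated classes are classified perfectly", {
  toy <- separable_classes(n_per_class = 20, delta = 6, seed = 42)
  split <- stratified_split(toy$y, 0.6, seed = 1)
  pred <- plsda_classify(toy$x[split$train, ], toy$y[split$train],
                         toy$x[split$validation, ], n_latent = 2)
  expect_equal(mean(pred == toy$y[split$validation]), 1.0)
  pred_c <- plsda_classify(toy$x[split$train, ], toy$y[split$train],
                           toy$x[split$validation, ], n_latent = 2,
                           rule = "centroid")
  expect_equal(mean(pred_c == toy$y[split$validation]), 1.0)
})

test_that("permuted labels drop accuracy to chance", {
  toy <- separable_classes(n_per_class = 20, delta = 6, seed = 42)
  accs <- sapply(1:20, function(s) {
    y_perm <- withr::with_seed(s, sample(toy$y))
    split <- stratified_split(y_perm, 0.6, seed = s)
    pred <- plsda_classify(toy$x[split$train, ], y_perm[split$train],
                           toy$x[split$validation, ], n_latent = 2)
    mean(pred == y_perm[split$validation])
  })
  n_total <- 20 * 16                       # 16 validation samples per run
  band <- 1.96 * sqrt(0.5 * 0.5 / n_total)
  expect_lt(abs(mean(accs) - 0.5), band + 0.05)
})

test_that("one latent variable on one feature matches the least-squares discriminant", {
  x <- matrix(c(1, 2, 3, 4, 10, 11, 12, 13), ncol = 1)
  colnames(x) <- "V1"
  y <- factor(rep(c("a", "b"), each = 4))
  fit <- plsda_fit(x, y, n_latent = 1)
  # closed-form oracle: OLS of each indicator on x; argmax switches where
  # the two fitted lines cross
  f_a <- stats::lm.fit(cbind(1, x), as.numeric(y == "a"))$coefficients
  f_b <- stats::lm.fit(cbind(1, x), as.numeric(y == "b"))$coefficients
  crossing <- (f_a[1] - f_b[1]) / (f_b[2] - f_a[2])
  probe <- matrix(seq(0, 14, by = 0.25), ncol = 1, dimnames = list(NULL, "V1"))
  off_tie <- abs(probe[, 1] - crossing) > 1e-6
  expected <- ifelse(probe[, 1] < crossing, "a", "b")
  expect_equal(as.character(predict(fit, probe))[off_tie],
               expected[off_tie], ignore_attr = TRUE)
  # an exact tie in the responses goes to the lowest class index
  tie <- matrix(mean(x), dimnames = list(NULL, "V1"))
  resp_tie <- predict(fit, tie, type = "response")
  expect_equal(unname(resp_tie[1, 1]), unname(resp_tie[1, 2]))
  expect_equal(as.character(predict(fit, tie)), "a")
})

test_that("NIPALS predictions agree with the reference PLS-DA", {
  toy <- separable_classes(n_per_class = 15, delta = 1.5, seed = 9)
  fit <- plsda_fit(toy$x, toy$y, n_latent = 2)
  ref <- suppressWarnings(
    mixOmics::plsda(toy$x, toy$y, ncomp = 2, scale = FALSE))
  pr <- predict(ref, toy$x)
  expect_equal(as.character(predict(fit, toy$x)),
               unname(pr$class$max.dist[, 2]))
  expect_equal(as.character(predict(fit, toy$x, rule = "centroid")),
               unname(pr$class$centroids.dist[, 2]))
})

test_that("PLS-DA enforces its dimensional limits and determinism", {
  toy <- separable_classes(n_per_class = 5, seed = 2)
  expect_error(plsda_fit(toy$x, toy$y, n_latent = 10), "exceeds")
  f1 <- plsda_fit(toy$x, toy$y, n_latent = 2)
  f2 <- plsda_fit(toy$x, toy$y, n_latent = 2)
  expect_identical(f1$coefficients, f2$coefficients)
})

test_that("random forest separates the toy classes reproducibly", {
  toy <- separable_classes(n_per_class = 20, delta = 6, seed = 42)
  split <- stratified_split(toy$y, 0.6, seed = 1)
  args <- list(toy$x[split$train, ], toy$y[split$train],
               toy$x[split$validation, ])
  pred1 <- do.call(rf_classify, c(args, n_trees = 100, seed = 7))
  pred2 <- do.call(rf_classify, c(args, n_trees = 100, seed = 7))
  expect_gte(mean(pred1 == toy$y[split$validation]), 0.95)
  expect_identical(pred1, pred2)
  single <- do.call(rf_classify, c(args, n_trees = 1, seed = 7))
  expect_equal(length(single), length(split$validation))
  expect_error(do.call(rf_classify, c(args, n_trees = 0)), ">= 1")
})
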
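#' Stratified train/validation split
#'
#' Allocates `round(train_fraction * n)` samples of every class to the
#' training set (clamped so each class keeps at least one sample on each
#' side) and the rest to validation. The two index sets are disjoint and
#' exhaustive, and the draw is reproducible for a fixed seed.
#'
#' @param labels class label per sample.
#' @param train_fraction fraction of each class assigned to training.
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `validation`.
#' @export
stratified_split <- function(labels, train_fraction = 0.6, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie strictly between 0 and 1")
  }
  labels <- as.character(labels)
  sizes <- table(labels)
  if (any(sizes < 2)) {
    small <- names(sizes)[sizes < 2]
    abort(paste0("class(es) with a single sample cannot be split: ",
                 paste(small, collapse = ", "),
                 "; merge classes or add replicates"))
  }
  train <- integer()
  withr::with_seed(seed, {
    for (cls in names(sizes)) {
      idx <- which(labels == cls)
      n_tr <- min(max(round(train_fraction * length(idx)), 1),
                  length(idx) - 1)
      train <- c(train, sample(idx, n_tr))
    }
  })
  train <- sort(train)
  list(train = train,
       validation = setdiff(seq_along(labels), train))
}

#' Evaluation protocol configuration
#'
#' Defaults mirror the study protocol: a 60/40 stratified
#' training/validation split, repeated three times, with PCA reduction ahead
#' of the classifiers.
#'
#' @param train_fraction training fraction of each class.
#' @param n_repeats number of independent seeded splits to average over.
#' @param n_components principal components fed to the classifiers; `NULL`
#'   selects the smallest number explaining at least `variance_target`
#'   percent of the variance, capped at 15.
#' @param variance_target cumulative explained-variance target (percent)
#'   used when `n_components` is `NULL`.
#' @param n_latent PLS-DA latent variables (capped at what the training set
#'   supports).
#' @param plsda_rule PLS-DA decision rule, `"centroid"` (default; robust to
#'   the interior-class masking of indicator regression) or `"max"`; see
#'   [predict.pupage_plsda()].
#' @param n_trees,max_features random-forest size and per-split feature
#'   count (default `floor(sqrt(p))`).
#' @param seed base RNG seed; repeat `r` uses `seed + r - 1`.
#' @return an `evaluation_config` list.
#' @export
evaluation_config <- function(train_fraction = 0.6, n_repeats = 3,
                              n_components = NULL, variance_target = 95,
                              n_latent = 5, plsda_rule = "centroid",
                              n_trees = 500, max_features = NULL, seed = 1) {
  if (n_repeats < 1) abort("n_repeats must be >= 1")
  structure(list(train_fraction = train_fraction, n_repeats = n_repeats,
                 n_components = n_components,
                 variance_target = variance_target, n_latent = n_latent,
                 plsda_rule = plsda_rule,
                 n_trees = n_trees, max_features = max_features,
                 seed = seed),
            class = "evaluation_config")
}

# Day-index classes sort numerically; the terminal EMPTY_PUPARIUM class
# sorts last.
order_age_classes <- function(x) {
  x <- unique(as.character(x))
  empty <- x == "EMPTY_PUPARIUM"
  c(x[!empty][order(suppressWarnings(as.numeric(x[!empty])))], x[empty])
}

#' Repeated split-and-classify evaluation of a spectral dataset
#'
#' Runs the full chemometric protocol: PCA reduction of the preprocessed
#' spectra, then for each of `n_repeats` seeded stratified splits, PLS-DA
#' and random-forest classification of the validation samples, a confusion
#' matrix and per-class/macro metrics, finally averaged across repeats.
#'
#' @param ds a preprocessed [spectral_dataset()] with at least two samples
#'   in every age class.
#' @param config an [evaluation_config()].
#' @return a `pupage_evaluation` with per-repeat reports and confusion
#'   matrices per model, the averaged metrics, and the number of components
#'   used. `tidy()` gives one row per (model, repeat, metric); `glance()`
#'   one row per model with averaged metrics.
#' @export
repeated_evaluation <- function(ds, config = evaluation_config()) {
  labels <- factor(ds$metadata$age_class,
                   levels = order_age_classes(ds$metadata$age_class))
  full <- spectra_pca(ds, n_components = 2)
  n_comp <- config$n_components %||% min(
    which(cumsum(full$all_variance_pct) >= config$variance_target)[1] %||%
      full$rank, 15, full$rank)
  if (is.na(n_comp)) n_comp <- min(15, full$rank)
  pca <- spectra_pca(ds, n_components = n_comp)
  x <- pca$scores

  models <- c("plsda", "rf")
  reports <- setNames(vector("list", 2), models)
  confusions <- setNames(vector("list", 2), models)
  for (r in seq_len(config$n_repeats)) {
    seed_r <- config$seed + r - 1
    split <- stratified_split(labels, config$train_fraction, seed = seed_r)
    tr_x <- x[split$train, , drop = FALSE]
    tr_y <- droplevels(labels[split$train])
    va_x <- x[split$validation, , drop = FALSE]
    va_y <- labels[split$validation]
    a <- min(config$n_latent, nrow(tr_x) - 1, ncol(tr_x))
    preds <- list(
      plsda = plsda_classify(tr_x, tr_y, va_x, n_latent = a,
                             rule = config$plsda_rule),
      rf = rf_classify(tr_x, tr_y, va_x, n_trees = config$n_trees,
                       max_features = config$max_features, seed = seed_r))
    for (m in models) {
      cm <- confusion_matrix(va_y, preds[[m]], classes = levels(labels))
      confusions[[m]][[r]] <- cm
      reports[[m]][[r]] <- classification_metrics(cm)
    }
  }

  averaged <- purrr::map_dfr(models, function(m) {
    g <- purrr::map_dfr(reports[[m]], glance)
    tibble(model = m,
           macro_accuracy = mean(g$macro_accuracy),
           macro_precision = mean(g$macro_precision),
           macro_recall = mean(g$macro_recall),
           macro_f1 = mean(g$macro_f1),
           micro_accuracy = mean(g$micro_accuracy),
           n_repeats = nrow(g))
  })
  structure(list(reports = reports, confusions = confusions,
                 averaged = averaged, n_components = n_comp,
                 classes = levels(labels), config = config),
            class = "pupage_evaluation")
}

#' @export
print.pupage_evaluation <- function(x, ...) {
  cat(sprintf(
    "<pupage_evaluation> %d repeats, %d PCs, classes: %s\n",
    x$config$n_repeats, x$n_components, paste(x$classes, collapse = ", ")))
  print(x$averaged)
  invisible(x)
}

#' @param x a `pupage_evaluation`.
#' @param ... unused.
#' @rdname repeated_evaluation
#' @exportS3Method generics::tidy
#' @export
tidy.pupage_evaluation <- function(x, ...) {
  purrr::map_dfr(names(x$reports), function(m) {
    purrr::map_dfr(seq_along(x$reports[[m]]), function(r) {
      mutate(glance(x$reports[[m]][[r]]), model = m, repeat_id = r,
             .before = 1)
    })
  })
}

#' @rdname repeated_evaluation
#' @exportS3Method generics::glance
#' @export
glance.pupage_evaluation <- function(x, ...) x$averaged
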
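#' Principal component analysis of a spectral dataset
#'
#' Reduces the samples-by-wavenumbers matrix by singular-value decomposition
#' of the column-centered data. Component `i` explains
#' `100 * sigma_i^2 / sum(sigma^2)` percent of the centered variance.
#' Results are deterministic up to component sign; the sign is fixed so the
#' largest-magnitude loading element of each component is positive.
#'
#' @param ds a [spectral_dataset()], normally the output of [preprocess()]
#'   (already mean-centered; centering here is idempotent).
#' @param n_components number of components to retain; at most the matrix
#'   rank.
#' @return a `pupage_pca` object with `scores` (samples x components),
#'   `loadings` (wavenumbers x components), `explained_variance_pct`,
#'   `cumulative_variance_pct`, and the sample `metadata`.
#' @export
spectra_pca <- function(ds, n_components = 2) {
  x <- t(ds$absorbance)                    # samples x wavenumbers
  if (nrow(x) < 2) abort("PCA needs >= 2 samples")
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (n_components > rank) {
    abort(sprintf("n_components = %d exceeds the matrix rank (%d)",
                  n_components, rank))
  }
  pct <- 100 * sv$d^2 / sum(sv$d^2)
  keep <- seq_len(n_components)
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], n_components)
  loadings <- sv$v[, keep, drop = FALSE]
  for (j in keep) {                        # sign convention
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(colnames(ds$absorbance), paste0("PC", keep))
  dimnames(loadings) <- list(ds$wavenumbers, paste0("PC", keep))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_pct = pct[keep],
                 cumulative_variance_pct = cumsum(pct)[keep],
                 all_variance_pct = pct[seq_len(rank)],
                 rank = rank, metadata = ds$metadata),
            class = "pupage_pca")
}

#' @export
print.pupage_pca <- function(x, ...) {
  cat(sprintf("<pupage_pca> %d components over %d samples\n",
              ncol(x$scores), nrow(x$scores)))
  print(tidy(x))
  invisible(x)
}

#' @param x a `pupage_pca`.
#' @param ... unused.
#' @return `tidy()` returns one row per retained component with its
#'   explained and cumulative variance percentages.
#' @rdname spectra_pca
#' @exportS3Method generics::tidy
#' @export
tidy.pupage_pca <- function(x, ...) {
  tibble(component = seq_along(x$explained_variance_pct),
         explained_variance_pct = x$explained_variance_pct,
         cumulative_variance_pct = x$cumulative_variance_pct)
}

#' Score plot of the first two principal components
#'
#' @param object a `pupage_pca` with at least two components.
#' @param colour_by metadata column mapped to point colour.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.pupage_pca <- function(object, colour_by = "age_class", ...) {
  if (ncol(object$scores) < 2) abort("score plot needs >= 2 components")
  df <- bind_cols(tibble(PC1 = object$scores[, 1],
                         PC2 = object$scores[, 2]),
                  object$metadata)
  pct <- object$explained_variance_pct
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data[[colour_by]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.2f%%)", pct[1]),
                  y = sprintf("PC2 (%.2f%%)", pct[2]))
}

#' Cumulative explained-variance bookkeeping
#'
#' Running totals of per-component explained-variance percentages, e.g. for
#' checking how many components clear a variance target (PC1 at 55.00% and
#' PC2 at 27.09% jointly explain 82.09%).
#'
#' @param pct per-component explained variance, in percent.
#' @return tibble with per-component and cumulative percentages.
#' @export
cumulative_variance <- function(pct) {
  if (any(pct < 0)) abort("variance percentages must be non-negative")
  tibble(component = seq_along(pct), explained_variance_pct = pct,
         cumulative_variance_pct = cumsum(pct))
}
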
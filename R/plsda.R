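#' Partial least squares discriminant analysis (NIPALS PLS2)
#'
#' Fits class membership by PLS2 regression of a one-hot class indicator
#' matrix on the feature matrix, extracting latent variables with the
#' NIPALS algorithm. Prediction assigns each sample to the class with the
#' largest predicted indicator response; exact ties go to the lowest class
#' index. The fit is fully deterministic.
#'
#' @param x numeric feature matrix, samples in rows (typically PCA scores).
#' @param y class labels (factor or character), one per row of `x`.
#' @param n_latent number of latent variables, at most
#'   `min(nrow(x) - 1, ncol(x))`.
#' @return a `pupage_plsda` model.
#' @export
plsda_fit <- function(x, y, n_latent = 5) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nrow(x) != length(y)) abort("x rows and y length differ")
  if (nlevels(y) < 2) abort("PLS-DA needs >= 2 classes")
  a_max <- min(nrow(x) - 1, ncol(x))
  if (n_latent > a_max) {
    abort(sprintf("n_latent = %d exceeds min(n-1, p) = %d", n_latent, a_max))
  }
  ymat <- stats::model.matrix(~ y - 1)     # one-hot, n x k
  colnames(ymat) <- levels(y)
  x_mean <- colMeans(x)
  y_mean <- colMeans(ymat)
  E <- sweep(x, 2, x_mean)
  F_ <- sweep(ymat, 2, y_mean)
  p <- ncol(E)
  k <- ncol(F_)
  W <- matrix(0, p, n_latent)
  P <- matrix(0, p, n_latent)
  Q <- matrix(0, k, n_latent)
  for (a in seq_len(n_latent)) {
    u <- F_[, which.max(apply(F_, 2, stats::var))]
    t_old <- rep(Inf, nrow(E))
    for (it in seq_len(500)) {
      w <- crossprod(E, u)
      w <- w / sqrt(sum(w^2))
      t_sc <- E %*% w
      q <- crossprod(F_, t_sc) / sum(t_sc^2)
      u <- F_ %*% q / sum(q^2)
      if (sqrt(sum((t_sc - t_old)^2)) < 1e-12 * sqrt(sum(t_sc^2))) break
      t_old <- t_sc
    }
    p_load <- crossprod(E, t_sc) / sum(t_sc^2)
    q_load <- crossprod(F_, t_sc) / sum(t_sc^2)
    E <- E - t_sc %*% t(p_load)
    F_ <- F_ - t_sc %*% t(q_load)
    W[, a] <- w
    P[, a] <- p_load
    Q[, a] <- q_load
  }
  # regression coefficients on the original (centered) X scale; R projects
  # centered X onto the latent scores (T = Xc R)
  R <- W %*% solve(crossprod(P, W))
  B <- R %*% t(Q)
  t_train <- sweep(x, 2, x_mean) %*% R
  centroids <- do.call(rbind, lapply(levels(y), function(cl) {
    colMeans(t_train[y == cl, , drop = FALSE])
  }))
  rownames(centroids) <- levels(y)
  structure(list(coefficients = B, x_mean = x_mean, y_mean = y_mean,
                 weights = W, x_loadings = P, y_loadings = Q,
                 projection = R, centroids = centroids,
                 classes = levels(y), n_latent = n_latent),
            class = "pupage_plsda")
}

#' @param object a `pupage_plsda` model.
#' @param newdata feature matrix with the same columns as the training `x`.
#' @param type `"class"` for hard assignments, `"response"` for the
#'   predicted indicator matrix.
#' @param rule decision rule for `type = "class"`: `"max"` assigns the
#'   class with the largest predicted indicator response (exact ties to the
#'   lowest class index); `"centroid"` assigns the nearest training-class
#'   centroid in latent score space. The max rule is the simplest reading of
#'   PLS-DA, but with more than two ordered classes it can mask interior
#'   classes (the classic indicator-regression masking effect); the centroid
#'   rule is robust to that and is the default for the evaluation protocol.
#' @param ... unused.
#' @rdname plsda_fit
#' @export
predict.pupage_plsda <- function(object, newdata,
                                 type = c("class", "response"),
                                 rule = c("max", "centroid"), ...) {
  type <- match.arg(type)
  rule <- match.arg(rule)
  newdata <- as.matrix(newdata)
  xc <- sweep(newdata, 2, object$x_mean)
  resp <- xc %*% object$coefficients
  resp <- sweep(resp, 2, object$y_mean, "+")
  colnames(resp) <- object$classes
  if (type == "response") return(resp)
  if (rule == "max") {
    idx <- apply(resp, 1, which.max)       # which.max: ties -> lowest index
  } else {
    scores <- xc %*% object$projection
    d2 <- vapply(seq_len(nrow(object$centroids)), function(i) {
      rowSums(sweep(scores, 2, object$centroids[i, ])^2)
    }, numeric(nrow(scores)))
    d2 <- matrix(d2, nrow = nrow(scores))
    idx <- apply(d2, 1, which.min)
  }
  factor(object$classes[idx], levels = object$classes)
}

#' @export
print.pupage_plsda <- function(x, ...) {
  cat(sprintf("<pupage_plsda> %d latent variables, %d classes (%s)\n",
              x$n_latent, length(x$classes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' One-call PLS-DA classification of a validation set
#'
#' @param train_x,train_y training features and labels.
#' @param val_x validation features.
#' @param n_latent number of latent variables.
#' @param rule decision rule, see [predict.pupage_plsda()].
#' @return factor of predicted classes for the validation rows.
#' @export
plsda_classify <- function(train_x, train_y, val_x, n_latent = 5,
                           rule = "max") {
  fit <- plsda_fit(train_x, train_y, n_latent = n_latent)
  predict(fit, val_x, rule = rule)
}

#' Random-forest classification of a validation set
#'
#' Majority vote over an ensemble of decision trees, each grown on a
#' bootstrap resample with random feature subsetting (delegated to
#' \pkg{randomForest}). Seeded, so identical calls give identical
#' predictions.
#'
#' @param train_x,train_y training features and labels.
#' @param val_x validation features.
#' @param n_trees number of trees (>= 1).
#' @param max_features features tried at each split; default
#'   `floor(sqrt(p))`.
#' @param seed RNG seed for reproducibility.
#' @return factor of predicted classes for the validation rows.
#' @export
rf_classify <- function(train_x, train_y, val_x, n_trees = 500,
                        max_features = NULL, seed = 1) {
  if (n_trees < 1) abort("n_trees must be >= 1")
  train_x <- as.matrix(train_x)
  val_x <- as.matrix(val_x)
  train_y <- as.factor(train_y)
  mtry <- max_features %||% max(1, floor(sqrt(ncol(train_x))))
  fit <- withr::with_seed(seed, randomForest::randomForest(
    x = train_x, y = train_y, ntree = n_trees, mtry = mtry))
  predict(fit, val_x)
}
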
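# Per-attribute linear models mapping a feature space to ratings, with
# repeated-random-split cross-validation to select the regularization
# strength. Ridge solutions are computed from the singular value
# decomposition of the standardized design matrix (exact L2 solution at
# every grid value at once); LASSO uses glmnet's coordinate descent; OLS
# has no tuning parameter and skips selection.

#' Configure model fitting
#'
#' @param method One of `"ridge"`, `"lasso"`, `"ols"`.
#' @param lambda_grid Strictly positive, sorted regularization grid.
#'   Defaults: ridge, 30 values log-spaced over `[1, 1e5]`; lasso, 30
#'   values log-spaced over `[0.01, 100]` (glmnet's penalty scale).
#'   Ignored for OLS. A single-value grid skips cross-validation.
#' @param n_cv_iterations Number of random splits (default 2000).
#' @param validation_fraction Held-out fraction per split (default 0.20).
#' @param selection_metric Validation metric minimized (maximized for
#'   `"r2"`) when averaging across splits: `"mse"` (default), `"r2"`, or
#'   `"rmse"`.
#' @param standardize Z-score features with training-fold statistics inside
#'   every fold, and with full-sample statistics at refit (default TRUE).
#'   Makes one grid meaningful across spaces of different scales.
#' @param seed Integer seed governing the split sequence; models fitted
#'   with the same config share the same splits, making selected
#'   regularization strengths comparable across attributes.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(method = c("ridge", "lasso", "ols"),
                       lambda_grid = NULL,
                       n_cv_iterations = 2000L,
                       validation_fraction = 0.20,
                       selection_metric = c("mse", "r2", "rmse"),
                       standardize = TRUE,
                       seed = 1L) {
  method <- match.arg(method)
  selection_metric <- match.arg(selection_metric)
  n_cv_iterations <- assert_count(n_cv_iterations, "n_cv_iterations")
  validation_fraction <- assert_proportion(validation_fraction, "validation_fraction")
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    fj_stop("validation_fraction must lie strictly between 0 and 1")
  }
  seed <- assert_count(seed, "seed", min = 0L)
  if (is.null(lambda_grid)) {
    lambda_grid <- switch(method,
                          ridge = 10^seq(0, 5, length.out = 30),
                          lasso = 10^seq(-2, 2, length.out = 30),
                          ols = numeric(0))
  }
  if (method != "ols") {
    if (length(lambda_grid) < 1L || any(lambda_grid <= 0)) {
      fj_stop("lambda_grid must be strictly positive")
    }
    if (is.unsorted(lambda_grid, strictly = TRUE)) {
      fj_stop("lambda_grid must be strictly increasing")
    }
  }
  structure(list(method = method, lambda_grid = as.numeric(lambda_grid),
                 n_cv_iterations = n_cv_iterations,
                 validation_fraction = validation_fraction,
                 selection_metric = selection_metric,
                 standardize = isTRUE(standardize), seed = seed),
            class = "fit_config")
}

# Exact ridge coefficients for all lambdas from one SVD:
# beta(l) = V diag(d / (d^2 + l)) U' y, the minimizer of
# ||y - X b||^2 + l ||b||^2. Returns p x n_lambda.
ridge_path_svd <- function(X, y, lambdas) {
  s <- svd(X)
  uty <- crossprod(s$u, y)
  coefs <- vapply(lambdas, function(l) {
    drop(s$v %*% (uty * s$d / (s$d^2 + l)))
  }, numeric(ncol(X)))
  matrix(coefs, nrow = ncol(X))
}

# Standardization statistics; constant columns are rejected because a
# z-scored constant is undefined and carries no signal.
std_stats <- function(X, standardize) {
  mu <- colMeans(X)
  if (standardize) {
    sdv <- apply(X, 2, stats::sd)
    zero <- which(sdv <= 0 | !is.finite(sdv))
    if (length(zero) > 0) {
      fj_stop("constant feature column(s): ",
              paste(utils::head(colnames(X)[zero], 5), collapse = ", "))
    }
  } else {
    sdv <- rep(1, ncol(X))
  }
  list(mean = mu, sd = sdv)
}

apply_std <- function(X, st) sweep(sweep(X, 2, st$mean), 2, st$sd, `/`)

# Coefficients at every grid value for one training fold. Returns a
# p x n_lambda matrix on the standardized-feature scale, plus intercepts.
fold_coefs <- function(Xs, y, config) {
  yc <- y - mean(y)
  if (config$method == "ridge") {
    W <- ridge_path_svd(Xs, yc, config$lambda_grid)
    list(W = W, a0 = rep(mean(y), length(config$lambda_grid)))
  } else if (config$method == "lasso") {
    grid <- rev(config$lambda_grid)    # glmnet expects decreasing lambda
    fit <- glmnet::glmnet(Xs, y, alpha = 1, lambda = grid,
                          standardize = FALSE, intercept = TRUE)
    cf <- as.matrix(stats::coef(fit, s = config$lambda_grid, exact = FALSE))
    list(W = cf[-1, , drop = FALSE], a0 = cf[1, ])
  } else {                              # ols
    fit <- stats::lm.fit(cbind(1, Xs), y)
    b <- fit$coefficients
    b[is.na(b)] <- 0                    # rank-deficient design: drop aliased terms
    list(W = matrix(b[-1], ncol = 1), a0 = b[1])
  }
}

# Mean validation error per grid value across splits; also tracks the mean
# validation-fold Spearman correlation per grid value (used by component
# count selection).
cv_curves <- function(X, y, config, splits) {
  n_lam <- max(1L, length(config$lambda_grid))
  err <- matrix(NA_real_, length(splits), n_lam)
  rho <- matrix(NA_real_, length(splits), n_lam)
  for (i in seq_along(splits)) {
    tr <- splits[[i]]$train; va <- splits[[i]]$val
    st <- std_stats(X[tr, , drop = FALSE], config$standardize)
    Xtr <- apply_std(X[tr, , drop = FALSE], st)
    Xva <- apply_std(X[va, , drop = FALSE], st)
    fc <- fold_coefs(Xtr, y[tr], config)
    pred <- sweep(Xva %*% fc$W, 2, fc$a0, `+`)
    res <- sweep(pred, 1, y[va])
    err[i, ] <- switch(config$selection_metric,
                       mse = colMeans(res^2),
                       rmse = sqrt(colMeans(res^2)),
                       r2 = 1 - colSums(res^2) / sum((y[va] - mean(y[va]))^2))
    rho[i, ] <- apply(pred, 2, function(p) {
      if (stats::sd(p) == 0 || stats::sd(y[va]) == 0) NA_real_
      else stats::cor(p, y[va], method = "spearman")
    })
  }
  list(error = colMeans(err), rho = colMeans(rho, na.rm = TRUE))
}

select_lambda <- function(curve, config) {
  score <- if (config$selection_metric == "r2") -curve$error else curve$error
  # smallest lambda among (near-)minimizers: no extra shrinkage is bought
  # for equal validation error
  which(score <= min(score) + 0)[1]
}

#' Fit one attribute's linear model
#'
#' For each cross-validation iteration a seeded random 80/20-style split is
#' drawn, every grid value is fit on the training part and scored on the
#' validation part; per-grid-value errors are averaged over iterations, the
#' minimizing value is selected (ties break to the smallest value), and the
#' model is refit at that value on all faces. OLS, and single-value grids,
#' skip selection.
#'
#' @param features A [feature_table()].
#' @param ratings A [rating_table()] covering the same faces.
#' @param attribute Attribute (column) to fit.
#' @param config A [fit_config()].
#' @param splits Optional precomputed split list (internal reuse across
#'   attributes).
#' @return An object of class `fitted_model`: standardized-scale `weights`,
#'   `intercept`, `lambda_selected`, the standardization statistics, the
#'   cross-validation error curve, and labels.
#' @export
fit_attribute_model <- function(features, ratings, attribute, config = fit_config(),
                                splits = NULL) {
  stopifnot(inherits(features, "feature_table"), inherits(ratings, "rating_table"),
            inherits(config, "fit_config"))
  if (!attribute %in% colnames(ratings$ratings)) {
    fj_stop("attribute '", attribute, "' not present in ratings")
  }
  features <- align_features(features, ratings$face_ids)
  n <- length(ratings$face_ids)
  if (n < 10L) fj_stop("need at least 10 faces to fit a model (got ", n, ")")
  y <- ratings$ratings[, attribute]
  if (stats::sd(y) == 0) fj_stop("rating column '", attribute, "' is constant")
  X <- features$features

  skip_cv <- config$method == "ols" || length(config$lambda_grid) == 1L
  curve <- NULL
  if (!skip_cv) {
    if (is.null(splits)) {
      splits <- make_cv_splits(n, config$n_cv_iterations,
                               config$validation_fraction, config$seed)
    }
    curve <- cv_curves(X, y, config, splits)
    idx <- select_lambda(curve, config)
    lambda <- config$lambda_grid[idx]
  } else {
    lambda <- if (config$method == "ols") NA_real_ else config$lambda_grid[1]
  }

  st <- std_stats(X, config$standardize)
  Xs <- apply_std(X, st)
  refit_cfg <- config
  refit_cfg$lambda_grid <- if (is.na(lambda)) numeric(0) else lambda
  fc <- fold_coefs(Xs, y, refit_cfg)
  weights <- drop(fc$W[, 1])
  names(weights) <- features$feature_names

  structure(list(attribute = attribute, space_name = features$space_name,
                 weights = weights, intercept = unname(fc$a0[1]),
                 lambda_selected = lambda, x_mean = st$mean, x_sd = st$sd,
                 method = config$method, standardize = config$standardize,
                 cv_error = curve$error, lambda_grid = config$lambda_grid,
                 n_faces = n),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> %s ~ %s (%s), %d features, lambda = %s\n",
              x$attribute, x$space_name, x$method, length(x$weights),
              format(x$lambda_selected)))
  invisible(x)
}

#' Predict ratings for faces from a fitted model
#'
#' Applies the stored standardization, weights and intercept. With
#' `flip_sign = TRUE` the weight contribution is negated (the intercept is
#' untouched), which predicts a semantically opposite (antonym) attribute;
#' rank-based evaluation is unaffected by the intercept.
#'
#' @param object A `fitted_model`.
#' @param features A [feature_table()] of the same space and
#'   dimensionality.
#' @param flip_sign Negate the weight contribution (antonym prediction).
#' @param ... Unused.
#' @return Named numeric vector of predicted ratings (one per face).
#' @export
predict.fitted_model <- function(object, features, flip_sign = FALSE, ...) {
  stopifnot(inherits(features, "feature_table"))
  if (!identical(object$space_name, features$space_name)) {
    fj_stop("feature space mismatch: model was fitted on '", object$space_name,
            "' but features are '", features$space_name,
            "' (cross-space application is not allowed)")
  }
  if (!identical(names(object$weights), features$feature_names)) {
    fj_stop("feature names/order differ from the model's training features")
  }
  Xs <- apply_std(features$features,
                  list(mean = object$x_mean, sd = object$x_sd))
  w <- if (flip_sign) -object$weights else object$weights
  preds <- drop(Xs %*% w) + object$intercept
  names(preds) <- features$face_ids
  preds
}

#' Fit models for every attribute of a rating table
#'
#' Delegates to [fit_attribute_model()] with one shared cross-validation
#' split sequence (same seed) across attributes, so selected
#' regularization strengths are comparable.
#'
#' @inheritParams fit_attribute_model
#' @param attributes Attributes to fit (default: all columns).
#' @return Named list of `fitted_model` objects.
#' @export
fit_all_attributes <- function(features, ratings, config = fit_config(),
                               attributes = colnames(ratings$ratings)) {
  stopifnot(inherits(ratings, "rating_table"))
  n <- length(ratings$face_ids)
  skip_cv <- config$method == "ols" || length(config$lambda_grid) == 1L
  splits <- if (!skip_cv) {
    make_cv_splits(n, config$n_cv_iterations, config$validation_fraction,
                   config$seed)
  }
  models <- lapply(attributes, function(a) {
    fit_attribute_model(features, ratings, a, config, splits = splits)
  })
  stats::setNames(models, attributes)
}

#' Serialize a fitted model to JSON (and back)
#'
#' @param model A `fitted_model`.
#' @param path JSON file path.
#' @return The model (reader) or the path, invisibly (writer).
#' @export
write_fitted_model <- function(model, path) {
  stopifnot(inherits(model, "fitted_model"))
  obj <- unclass(model)
  obj$feature_names <- names(model$weights)
  for (f in c("weights", "x_mean", "x_sd")) obj[[f]] <- unname(obj[[f]])
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_fitted_model
#' @export
read_fitted_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$lambda_selected <- obj$lambda_selected %||% NA_real_
  for (f in c("weights", "x_mean", "x_sd")) {
    obj[[f]] <- stats::setNames(obj[[f]], obj$feature_names)
  }
  structure(obj, class = "fitted_model")
}
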
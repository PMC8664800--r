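# Variance partitioning between two feature spaces: fit a model on space
# A, a model on space B, and a model on their concatenation (same
# cross-validation protocol, jointly re-standardized); compute
# out-of-sample R-squared for each; and decompose into
#   unique_a = r2_joint - r2_b
#   unique_b = r2_joint - r2_a
#   shared   = r2_a + r2_b - r2_joint
# which satisfy unique_a + unique_b + shared = r2_joint exactly.
# Out-of-sample components can be negative; they are reported as-is so
# that the identity holds.

concat_feature_tables <- function(a, b) {
  if (identical(a$space_name, b$space_name)) {
    fj_stop("the two feature spaces must be distinct (both are '", a$space_name, "')")
  }
  b <- align_features(b, a$face_ids)
  overlap <- intersect(a$feature_names, b$feature_names)
  if (length(overlap) > 0) {
    fj_stop("overlapping feature names between spaces (e.g. '", overlap[1],
            "'); disambiguate before concatenation")
  }
  feature_table(paste0(a$space_name, "+", b$space_name),
                cbind(a$features, b$features), a$face_ids,
                c(a$feature_names, b$feature_names))
}

r_squared <- function(actual, predicted, baseline_mean = mean(actual)) {
  1 - sum((actual - predicted)^2) / sum((actual - baseline_mean)^2)
}

partition_components <- function(r2_a, r2_b, r2_joint) {
  c(unique_a = r2_joint - r2_b,
    unique_b = r2_joint - r2_a,
    shared = r2_a + r2_b - r2_joint)
}

#' Partition out-of-sample explained variance between two feature spaces
#'
#' Fits three models on the training data with the same cross-validation
#' protocol and split sequence: one per space and one on the concatenated
#' features (re-standardized jointly, same regularization grid). Each
#' model predicts the test set; explained variance is the coefficient of
#' determination `1 - SSE/SST` with SST about the test-sample mean (or the
#' training mean, if `baseline = "train"`). The unique and shared
#' components follow by the three identities above.
#'
#' @param ratings_train Training [rating_table()].
#' @param feats_a,feats_b Training [feature_table()]s for spaces A and B
#'   (distinct names, disjoint feature names).
#' @param ratings_test,test_a,test_b Test-set counterparts.
#' @param attribute Attribute to partition.
#' @param config A [fit_config()].
#' @param baseline `"test"` (default) or `"train"`: which sample mean
#'   anchors SST.
#' @return An object of class `variance_partition` with `r2_a`, `r2_b`,
#'   `r2_joint`, `unique_a`, `unique_b`, `shared`, labels, and the three
#'   test-set prediction vectors (reused by [bootstrap_partition()]).
#' @export
partition_variance <- function(ratings_train, feats_a, feats_b,
                               ratings_test, test_a, test_b,
                               attribute, config = fit_config(),
                               baseline = c("test", "train")) {
  baseline <- match.arg(baseline)
  feats_joint <- concat_feature_tables(feats_a, feats_b)
  test_joint <- concat_feature_tables(test_a, test_b)
  n <- length(ratings_train$face_ids)
  skip_cv <- config$method == "ols" || length(config$lambda_grid) == 1L
  splits <- if (!skip_cv) {
    make_cv_splits(n, config$n_cv_iterations, config$validation_fraction,
                   config$seed)
  }
  m_a <- fit_attribute_model(feats_a, ratings_train, attribute, config, splits)
  m_b <- fit_attribute_model(feats_b, ratings_train, attribute, config, splits)
  m_j <- fit_attribute_model(feats_joint, ratings_train, attribute, config, splits)
  test_a <- align_features(test_a, ratings_test$face_ids)
  test_b <- align_features(test_b, ratings_test$face_ids)
  test_joint <- align_features(test_joint, ratings_test$face_ids)
  y <- ratings_test$ratings[, attribute]
  preds <- list(a = predict(m_a, test_a), b = predict(m_b, test_b),
                joint = predict(m_j, test_joint))
  mu <- if (baseline == "test") mean(y) else mean(ratings_train$ratings[, attribute])
  r2 <- vapply(preds, function(p) r_squared(y, p, mu), numeric(1))
  comp <- partition_components(r2[["a"]], r2[["b"]], r2[["joint"]])
  structure(list(attribute = attribute,
                 space_a = feats_a$space_name, space_b = feats_b$space_name,
                 r2_a = r2[["a"]], r2_b = r2[["b"]], r2_joint = r2[["joint"]],
                 unique_a = comp[["unique_a"]], unique_b = comp[["unique_b"]],
                 shared = comp[["shared"]], baseline = baseline,
                 predictions = preds, actual = y),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("<variance_partition> '%s': %s vs %s\n", x$attribute,
              x$space_a, x$space_b))
  cat(sprintf("  r2_a = %.4f, r2_b = %.4f, r2_joint = %.4f\n",
              x$r2_a, x$r2_b, x$r2_joint))
  cat(sprintf("  unique_a = %.4f, unique_b = %.4f, shared = %.4f\n",
              x$unique_a, x$unique_b, x$shared))
  invisible(x)
}

#' Bootstrap uncertainty for a variance partition
#'
#' The three models are fitted once on the training data; test faces are
#' then resampled with replacement, and the three R-squared values and the
#' derived components are recomputed per resample (SST about the
#' resample's own mean under the `"test"` baseline). Component p-values
#' are one-sided bootstrap probabilities of the component crossing zero,
#' oriented by the sign of the point estimate; pairwise component
#' differences are tested the same way. FDR correction across attributes
#' is left to the caller, where the family lives.
#'
#' @inheritParams partition_variance
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @return A `variance_partition` with added `boot_sd`, `p_boot` (per
#'   component), `diff_p` (pairwise component differences), `n_boot`, and
#'   the per-draw component matrix `draws`.
#' @export
bootstrap_partition <- function(ratings_train, feats_a, feats_b,
                                ratings_test, test_a, test_b,
                                attribute, config = fit_config(),
                                baseline = c("test", "train"),
                                n_boot = 1000L, seed = 1L) {
  baseline <- match.arg(baseline)
  n_boot <- assert_count(n_boot, "n_boot", min = 100L)
  part <- partition_variance(ratings_train, feats_a, feats_b, ratings_test,
                             test_a, test_b, attribute, config, baseline)
  y <- part$actual
  n <- length(y)
  train_mu <- mean(ratings_train$ratings[, attribute])
  draws <- withr::with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, replace = TRUE)
      yb <- y[idx]
      if (stats::sd(yb) == 0) return(rep(NA_real_, 6))
      mu <- if (baseline == "test") mean(yb) else train_mu
      r2 <- vapply(part$predictions, function(p) r_squared(yb, p[idx], mu),
                   numeric(1))
      comp <- partition_components(r2[["a"]], r2[["b"]], r2[["joint"]])
      c(r2_a = r2[["a"]], r2_b = r2[["b"]], r2_joint = r2[["joint"]], comp)
    }, numeric(6)))
  })
  ok <- stats::complete.cases(draws)
  if (!any(ok)) fj_stop("all bootstrap resamples were degenerate (constant ratings)")
  comp_names <- c("unique_a", "unique_b", "shared")
  est <- unlist(part[comp_names])
  p_boot <- vapply(comp_names, function(cn) {
    d <- draws[ok, cn]
    if (est[[cn]] >= 0) mean(d <= 0) else mean(d >= 0)
  }, numeric(1))
  pairs <- utils::combn(comp_names, 2, simplify = FALSE)
  diff_p <- vapply(pairs, function(pr) {
    d <- draws[ok, pr[1]] - draws[ok, pr[2]]
    e <- est[[pr[1]]] - est[[pr[2]]]
    if (e >= 0) mean(d <= 0) else mean(d >= 0)
  }, numeric(1))
  names(diff_p) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  part$boot_sd <- apply(draws[ok, comp_names, drop = FALSE], 2, stats::sd)
  part$p_boot <- p_boot
  part$diff_p <- diff_p
  part$n_boot <- n_boot
  part$n_skipped <- sum(!ok)
  part$draws <- draws
  part
}

#' Tidy a set of variance partitions into a long data frame
#'
#' @param partitions List of `variance_partition` objects (typically one
#'   per attribute), as produced by [bootstrap_partition()].
#' @param alpha FDR level applied across all component p-values.
#' @return Data frame: one row per attribute per component, with bootstrap
#'   SD, p, q and significance when available.
#' @export
partition_table <- function(partitions, alpha = 0.05) {
  rows <- lapply(partitions, function(p) {
    comp <- c("unique_a", "unique_b", "shared")
    data.frame(attribute = p$attribute, space_a = p$space_a, space_b = p$space_b,
               component = comp,
               estimate = unlist(p[comp], use.names = FALSE),
               boot_sd = if (is.null(p$boot_sd)) NA_real_ else unname(p$boot_sd[comp]),
               p_boot = if (is.null(p$p_boot)) NA_real_ else unname(p$p_boot[comp]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!all(is.na(out$p_boot))) {
    out$q_fdr <- fdr_adjust(out$p_boot)
    out$significant <- out$q_fdr < alpha
  }
  out
}
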
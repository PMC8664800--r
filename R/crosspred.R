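# Prediction-specificity auditing: the full matrix of (model trained on
# attribute i) x (human ratings of attribute j), its permutation
# significance with the whole matrix as the FDR family, semi-partial
# residual cross-predictions that control a third attribute's model, and
# the dataset-level summary statistics. Test attributes need not have a
# trained model, so the matrix is rectangular in general.

cross_cells <- function(pred_mat, test_ratings, n_boot, n_perm, alpha, seed,
                        identity_map = NULL, smooth = FALSE) {
  model_attrs <- colnames(pred_mat)
  test_attrs <- colnames(test_ratings$ratings)
  rows <- list()
  for (ta in test_attrs) {
    actual <- test_ratings$ratings[, ta]
    for (ma in model_attrs) {
      preds <- pred_mat[, ma]
      cell_seed <- derive_seed(seed, paste0(ta, "|", ma))
      if (stats::sd(preds) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          test_attribute = ta, model_attribute = ma, mean_rho = NA_real_,
          boot_sd = NA_real_, chance_threshold = NA_real_, p_perm = NA_real_,
          observed_rho = NA_real_, degenerate = TRUE, stringsAsFactors = FALSE)
        next
      }
      boot <- bootstrap_accuracy(preds, actual, identity_map = identity_map,
                                 n_boot = n_boot, seed = cell_seed)
      perm <- permutation_null(preds, actual, n_perm = n_perm,
                               seed = derive_seed(cell_seed, "perm"),
                               smooth = smooth)
      rows[[length(rows) + 1L]] <- data.frame(
        test_attribute = ta, model_attribute = ma,
        mean_rho = boot$mean_rho, boot_sd = boot$boot_sd,
        chance_threshold = perm$chance_threshold, p_perm = perm$p_perm,
        observed_rho = perm$observed_rho, degenerate = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, rows)
  ok <- !cells$degenerate
  cells$q_fdr <- NA_real_
  cells$q_fdr[ok] <- fdr_adjust(cells$p_perm[ok])   # family: all scored cells
  cells$significant <- !is.na(cells$q_fdr) & cells$q_fdr < alpha
  cells$row_max <- FALSE
  for (ta in unique(cells$test_attribute)) {
    sel <- which(cells$test_attribute == ta & ok)
    if (length(sel) > 0) {
      cells$row_max[sel[which.max(abs(cells$mean_rho[sel]))]] <- TRUE
    }
  }
  cells
}

#' Cross-prediction specificity matrix
#'
#' Every fitted model (columns) predicts the test faces once; each
#' prediction vector is then scored against the human ratings of every
#' test attribute (rows) with bootstrap accuracy and a permutation null.
#' FDR correction treats all cells of the matrix as one family. The
#' highest-|rho| cell per row is flagged: if a row's best predictor is a
#' model trained on a different attribute, the predictions are not
#' attribute-specific.
#'
#' @param models Named list of `fitted_model`s sharing one feature space.
#' @param test_ratings Test-set [rating_table()] (may include attributes
#'   with no trained model).
#' @param test_features Test-set [feature_table()] of the models' space.
#' @param n_boot,n_perm,alpha,seed,identity_map,smooth As in
#'   [evaluate_models()].
#' @return Object of class `cross_prediction_matrix`: long data frame
#'   `cells` (one row per matrix cell, with `row_max` flags), the
#'   prediction matrix, and labels.
#' @export
cross_prediction_matrix <- function(models, test_ratings, test_features,
                                    n_boot = 1000L, n_perm = 1000L,
                                    alpha = 0.05, seed = 1L,
                                    identity_map = NULL, smooth = FALSE) {
  stopifnot(length(models) >= 1L)
  spaces <- unique(vapply(models, `[[`, character(1), "space_name"))
  if (length(spaces) != 1L) {
    fj_stop("all models must share one feature space (got: ",
            paste(spaces, collapse = ", "), ")")
  }
  test_features <- align_features(test_features, test_ratings$face_ids)
  pred_mat <- vapply(models, predict, numeric(length(test_ratings$face_ids)),
                     features = test_features)
  colnames(pred_mat) <- names(models)
  cells <- cross_cells(pred_mat, test_ratings, n_boot, n_perm, alpha, seed,
                       identity_map, smooth)
  structure(list(cells = cells, predictions = pred_mat,
                 model_attributes = names(models),
                 test_attributes = colnames(test_ratings$ratings),
                 space_name = spaces, alpha = alpha),
            class = "cross_prediction_matrix")
}

#' @export
print.cross_prediction_matrix <- function(x, ...) {
  cat(sprintf("<cross_prediction_matrix> %d test attributes x %d models ('%s')\n",
              length(x$test_attributes), length(x$model_attributes), x$space_name))
  cat(sprintf("  significant cells: %d / %d\n", sum(x$cells$significant),
              nrow(x$cells)))
  invisible(x)
}

#' Semi-partial residual cross-prediction matrix
#'
#' Measures what remains of each cross-prediction after the control
#' model's predictions are partialed out of the predicting model's
#' predictions (semi-partial: the control is removed from Y only, not from
#' the human ratings X). For each non-control model, Y (its predictions)
#' is regressed on Z (the control model's predictions) by ordinary least
#' squares on the raw predicted scores; the residuals are then
#' rank-correlated with the human ratings of every test attribute, with
#' bootstrap and permutation inference as in the raw matrix. A constant Z
#' cannot absorb anything: residuals are then the centered Y and the
#' matrix reduces to the raw one. A model whose predictions are fully
#' absorbed by the control (near-zero residual variance) is flagged
#' degenerate and not scored.
#'
#' @inheritParams cross_prediction_matrix
#' @param control_attribute Name of the fitted model to partial out; its
#'   column is absent from the residual matrix.
#' @return Object of class `semi_partial_result`: residual `cells`,
#'   `control_attribute`, and the three dataset-level summaries
#'   (`mean_abs_rho`, `mean_row_max_abs_rho`, `frac_significant`,
#'   computed excluding same-attribute pairs).
#' @export
semi_partial_residual_matrix <- function(models, test_ratings, test_features,
                                         control_attribute,
                                         n_boot = 1000L, n_perm = 1000L,
                                         alpha = 0.05, seed = 1L,
                                         identity_map = NULL, smooth = FALSE) {
  if (!control_attribute %in% names(models)) {
    fj_stop("no fitted model for control attribute '", control_attribute, "'")
  }
  others <- setdiff(names(models), control_attribute)
  if (length(others) < 2L) {
    fj_stop("need at least 2 non-control models for a residual matrix")
  }
  test_features <- align_features(test_features, test_ratings$face_ids)
  z <- predict(models[[control_attribute]], test_features)
  resid_mat <- vapply(others, function(ma) {
    y <- predict(models[[ma]], test_features)
    residualize(y, z)
  }, numeric(length(test_ratings$face_ids)))
  colnames(resid_mat) <- others
  cells <- cross_cells(resid_mat, test_ratings, n_boot, n_perm, alpha,
                       derive_seed(seed, paste0("sp|", control_attribute)),
                       identity_map, smooth)
  structure(list(cells = cells, control_attribute = control_attribute,
                 model_attributes = others,
                 test_attributes = colnames(test_ratings$ratings),
                 summaries = summarize_cells(cells), alpha = alpha),
            class = "semi_partial_result")
}

# OLS residuals of y on z (with intercept). Constant z regresses on the
# intercept alone, leaving centered y: rank correlations are unchanged, so
# a zero-weight control model is a no-op, as it should be. Residuals that
# are numerically zero relative to y's scale are returned as an exact zero
# vector so downstream scoring flags the cell degenerate.
residualize <- function(y, z) {
  if (stats::sd(z) == 0) return(y - mean(y))
  b <- stats::cov(y, z) / stats::var(z)
  r <- y - mean(y) - b * (z - mean(z))
  if (stats::sd(r) < 1e-10 * max(stats::sd(y), .Machine$double.eps)) {
    r[] <- 0
  }
  r
}

# Dataset-level summaries over scored cross-prediction cells, excluding
# same-attribute (self-prediction) pairs.
summarize_cells <- function(cells) {
  cross <- cells[!cells$degenerate &
                   cells$test_attribute != cells$model_attribute, , drop = FALSE]
  if (nrow(cross) == 0) {
    return(c(mean_abs_rho = 0, mean_row_max_abs_rho = 0, frac_significant = 0))
  }
  row_max <- vapply(split(abs(cross$mean_rho), cross$test_attribute), max,
                    numeric(1))
  c(mean_abs_rho = mean(abs(cross$mean_rho)),
    mean_row_max_abs_rho = mean(row_max),
    frac_significant = mean(cross$significant))
}

#' Dataset-level cross-prediction summaries
#'
#' Per control attribute (plus `"none"` for the raw matrix): the mean
#' absolute cross-prediction accuracy over all cells, the mean per-row
#' maximum absolute accuracy, and the fraction of significant cells.
#' Same-attribute (self-prediction) pairs are excluded from all three.
#' The control minimizing the mean residual accuracy — the attribute whose
#' model carries most of the cross-prediction structure — is marked.
#'
#' @param matrix A [cross_prediction_matrix()] result.
#' @param residuals List of [semi_partial_residual_matrix()] results.
#' @return Data frame: one row per control (first row `"none"`), columns
#'   `mean_abs_rho`, `mean_row_max_abs_rho`, `frac_significant`,
#'   `most_impactful`.
#' @export
cross_prediction_summaries <- function(matrix, residuals = list()) {
  stopifnot(inherits(matrix, "cross_prediction_matrix"))
  rows <- list(data.frame(control = "none",
                          t(summarize_cells(matrix$cells)),
                          stringsAsFactors = FALSE))
  for (res in residuals) {
    stopifnot(inherits(res, "semi_partial_result"))
    rows[[length(rows) + 1L]] <- data.frame(control = res$control_attribute,
                                            t(res$summaries),
                                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$most_impactful <- FALSE
  if (nrow(out) > 1L) {
    ctrl <- out[-1, ]
    out$most_impactful[1 + which.min(ctrl$mean_abs_rho)] <- TRUE
  }
  out
}

#' Write cross-prediction cells to CSV (long format)
#'
#' @param x A `cross_prediction_matrix` or `semi_partial_result`.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_cross_prediction_csv <- function(x, path) {
  cells <- x$cells
  if (inherits(x, "semi_partial_result")) cells$control <- x$control_attribute
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}
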
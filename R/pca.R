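# Dimensionality reduction for high-dimensional feature spaces (e.g.
# flattened convolutional activations): fit a PCA basis on a reference
# face set, project training and test faces onto it, and select the number
# of components by cross-validated predictive accuracy on the training
# ratings only. The reference set and the basis never see any test-set
# ratings.

#' Fit a PCA basis on a reference feature table
#'
#' Components are computed from the centered (not scaled) reference data
#' and ordered by decreasing explained variance. Features within one space
#' share units, so no per-feature rescaling is applied.
#'
#' @param reference A [feature_table()] of reference faces.
#' @param n_components Number of components to retain; at most
#'   `min(n_faces - 1, n_features)`.
#' @return An object of class `pc_basis`: `mean_vector`, `components`
#'   (orthonormal rows, `n_components x n_features`), per-component
#'   standard deviations, and the reference label.
#' @export
fit_pca_basis <- function(reference, n_components) {
  stopifnot(inherits(reference, "feature_table"))
  n_components <- assert_count(n_components, "n_components")
  n_max <- min(nrow(reference$features) - 1L, ncol(reference$features))
  if (n_components > n_max) {
    fj_stop("n_components = ", n_components, " exceeds min(n_faces - 1, n_features) = ", n_max)
  }
  pc <- stats::prcomp(reference$features, center = TRUE, scale. = FALSE)
  comps <- t(pc$rotation[, seq_len(n_components), drop = FALSE])
  rownames(comps) <- paste0("PC", seq_len(n_components))
  structure(list(mean_vector = pc$center,
                 components = comps,
                 sdev = pc$sdev[seq_len(n_components)],
                 n_components = n_components,
                 space_name = reference$space_name,
                 fitted_on = paste0(reference$space_name, ":", nrow(reference$features), "faces"),
                 feature_names = reference$feature_names),
            class = "pc_basis")
}

#' @export
print.pc_basis <- function(x, ...) {
  cat(sprintf("<pc_basis> %d components over %d '%s' features (ref: %s)\n",
              x$n_components, length(x$mean_vector), x$space_name, x$fitted_on))
  invisible(x)
}

#' Project a feature table onto a PCA basis
#'
#' Projection subtracts the basis mean (the reference mean, not the
#' projected set's own mean) and applies the component matrix. The
#' resulting score table is a new feature space named
#' `"<space>:pca<k>"`; training and test sets projected through the same
#' basis therefore share a space name and are interchangeable for a fitted
#' model.
#'
#' @param features A [feature_table()] with the basis' dimensionality and
#'   space name.
#' @param basis A [fit_pca_basis()] result.
#' @param n_components Optionally use only the first `n_components` rows of
#'   the basis (component nesting).
#' @return A [feature_table()] of PC scores.
#' @export
project_features <- function(features, basis, n_components = basis$n_components) {
  stopifnot(inherits(features, "feature_table"), inherits(basis, "pc_basis"))
  if (!identical(features$space_name, basis$space_name)) {
    fj_stop("feature space mismatch: table is '", features$space_name,
            "' but basis was fitted on '", basis$space_name, "'")
  }
  if (ncol(features$features) != length(basis$mean_vector)) {
    fj_stop("dimension mismatch: table has ", ncol(features$features),
            " features, basis expects ", length(basis$mean_vector))
  }
  n_components <- assert_count(n_components, "n_components")
  if (n_components > basis$n_components) {
    fj_stop("basis only holds ", basis$n_components, " components")
  }
  comps <- basis$components[seq_len(n_components), , drop = FALSE]
  scores <- sweep(features$features, 2, basis$mean_vector) %*% t(comps)
  colnames(scores) <- rownames(comps)
  feature_table(paste0(features$space_name, ":pca", n_components),
                scores, features$face_ids)
}

#' Select the number of principal components by predictive accuracy
#'
#' Scans candidate component counts: for each count, training features are
#' projected onto the leading components of the reference-set basis and a
#' per-attribute model is fitted with the usual cross-validated
#' regularization selection; the candidate's accuracy is the mean (across
#' attributes) validation-fold Spearman correlation at the selected
#' regularization strength. The count maximizing mean accuracy is
#' returned; ties (within `tie_tolerance`) break toward the smaller count.
#' Only training-set ratings are consulted.
#'
#' @param reference Reference [feature_table()] for the PCA basis.
#' @param train_ratings Training [rating_table()].
#' @param train_features Training [feature_table()] (same raw space as
#'   `reference`).
#' @param scan_min,scan_max,step Candidate counts `seq(scan_min, scan_max,
#'   step)`.
#' @param config A [fit_config()] used for every candidate.
#' @param tie_tolerance Accuracies within this of the maximum count as
#'   tied.
#' @return The selected component count (integer), with the per-candidate
#'   mean accuracies attached as attribute `"accuracy"`.
#' @export
select_num_components <- function(reference, train_ratings, train_features,
                                  scan_min, scan_max, step = 1L,
                                  config = fit_config(),
                                  tie_tolerance = 1e-9) {
  scan_min <- assert_count(scan_min, "scan_min")
  scan_max <- assert_count(scan_max, "scan_max")
  step <- assert_count(step, "step")
  if (scan_max < scan_min) fj_stop("empty scan range")
  candidates <- seq.int(scan_min, scan_max, by = step)
  n_max <- min(nrow(reference$features) - 1L, ncol(reference$features))
  if (scan_max > n_max) {
    fj_stop("scan_max = ", scan_max, " is infeasible: at most ", n_max,
            " components are available from the reference set")
  }
  basis <- fit_pca_basis(reference, scan_max)
  train_features <- align_features(train_features, train_ratings$face_ids)
  n <- length(train_ratings$face_ids)
  splits <- make_cv_splits(n, config$n_cv_iterations,
                           config$validation_fraction, config$seed)
  attrs <- colnames(train_ratings$ratings)
  acc <- vapply(candidates, function(k) {
    scores <- project_features(train_features, basis, k)
    mean(vapply(attrs, function(a) {
      y <- train_ratings$ratings[, a]
      curve <- cv_curves(scores$features, y, config, splits)
      if (config$method == "ols" || length(config$lambda_grid) == 1L) {
        curve$rho[1]
      } else {
        curve$rho[select_lambda(curve, config)]
      }
    }, numeric(1)))
  }, numeric(1))
  best <- max(acc)
  selected <- candidates[which(acc >= best - tie_tolerance)[1]]
  structure(as.integer(selected), accuracy = stats::setNames(acc, candidates))
}

#' Serialize a PCA basis to JSON (and back)
#'
#' @param basis A `pc_basis`.
#' @param path JSON file path.
#' @return The basis (reader) or the path, invisibly (writer).
#' @export
write_pc_basis <- function(basis, path) {
  stopifnot(inherits(basis, "pc_basis"))
  obj <- list(mean_vector = unname(basis$mean_vector),
              components = apply(basis$components, 1, as.numeric, simplify = FALSE),
              sdev = basis$sdev, n_components = basis$n_components,
              space_name = basis$space_name, fitted_on = basis$fitted_on,
              feature_names = basis$feature_names)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pc_basis
#' @export
read_pc_basis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  comps <- do.call(rbind, obj$components)
  dimnames(comps) <- list(paste0("PC", seq_len(nrow(comps))), obj$feature_names)
  structure(list(mean_vector = stats::setNames(obj$mean_vector, obj$feature_names),
                 components = comps, sdev = obj$sdev,
                 n_components = obj$n_components, space_name = obj$space_name,
                 fitted_on = obj$fitted_on, feature_names = obj$feature_names),
            class = "pc_basis")
}
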
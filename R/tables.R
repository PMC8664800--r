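# Core data containers: rating tables (faces x social attributes) and
# feature tables (faces x numeric features for one named feature space).

#' Construct a rating table
#'
#' A rating table holds mean human ratings (averaged across raters) of a set
#' of faces on one or more social attributes, on a bounded Likert scale.
#' Rows are faces, columns are attributes. These are the regression targets
#' and the evaluation ground truth throughout the package.
#'
#' @param ratings Numeric matrix (faces x attributes) with column names.
#' @param face_ids Character vector of unique face identifiers; defaults to
#'   the matrix row names.
#' @param likert_min,likert_max Scale bounds the ratings are declared on
#'   (default 1 and 7). Values outside the bounds trigger a warning but are
#'   retained, since upstream averaging or imputation can produce them.
#' @return An object of class `rating_table`.
#' @export
rating_table <- function(ratings, face_ids = rownames(ratings),
                         likert_min = 1, likert_max = 7) {
  ratings <- as.matrix(ratings)
  if (!is.numeric(ratings)) fj_stop("ratings must be numeric")
  if (is.null(colnames(ratings))) fj_stop("ratings must have attribute column names")
  if (is.null(face_ids)) fj_stop("face_ids are required (or set rownames)")
  face_ids <- as.character(face_ids)
  if (length(face_ids) != nrow(ratings)) {
    fj_stop("length(face_ids) must equal nrow(ratings)")
  }
  if (anyDuplicated(face_ids)) {
    fj_stop("duplicate face_id: ", paste(unique(face_ids[duplicated(face_ids)]), collapse = ", "))
  }
  bad <- which(!is.finite(ratings), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    fj_stop(sprintf("non-finite rating at row %d (face '%s'), column '%s'",
                    bad[1, 1], face_ids[bad[1, 1]], colnames(ratings)[bad[1, 2]]))
  }
  if (any(ratings < likert_min | ratings > likert_max)) {
    out <- which(ratings < likert_min | ratings > likert_max, arr.ind = TRUE)
    warning(sprintf(
      "%d rating(s) outside the declared [%g, %g] scale (first: face '%s', attribute '%s', value %g); values retained",
      nrow(out), likert_min, likert_max,
      face_ids[out[1, 1]], colnames(ratings)[out[1, 2]], ratings[out[1, 1], out[1, 2]]),
      call. = FALSE)
  }
  rownames(ratings) <- face_ids
  structure(list(face_ids = face_ids, ratings = ratings,
                 likert_min = likert_min, likert_max = likert_max),
            class = "rating_table")
}

#' Construct a feature table
#'
#' A feature table holds a numeric faces x features matrix for one named
#' feature space (e.g. an identity-embedding space, PCA-reduced
#' convolutional activations, or landmark-derived facial geometry). It is
#' the regression design matrix.
#'
#' @param space_name Label of the feature space.
#' @param features Numeric matrix (faces x features), no missing values.
#' @param face_ids Unique face identifiers (default: row names).
#' @param feature_names Column labels (default: existing column names, or
#'   `f1..fp`).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(space_name, features, face_ids = rownames(features),
                          feature_names = colnames(features)) {
  features <- as.matrix(features)
  if (!is.numeric(features)) fj_stop("features must be numeric")
  if (ncol(features) < 1L) fj_stop("feature table needs at least one column")
  if (is.null(face_ids)) fj_stop("face_ids are required (or set rownames)")
  face_ids <- as.character(face_ids)
  if (length(face_ids) != nrow(features)) {
    fj_stop("length(face_ids) must equal nrow(features)")
  }
  if (anyDuplicated(face_ids)) {
    fj_stop("duplicate face_id: ", paste(unique(face_ids[duplicated(face_ids)]), collapse = ", "))
  }
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(features)))
  feature_names <- as.character(feature_names)
  if (anyDuplicated(feature_names)) fj_stop("duplicate feature names")
  bad <- which(!is.finite(features), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    fj_stop(sprintf("non-finite feature value at row %d (face '%s'), column '%s'",
                    bad[1, 1], face_ids[bad[1, 1]], feature_names[bad[1, 2]]))
  }
  dimnames(features) <- list(face_ids, feature_names)
  structure(list(space_name = as.character(space_name), face_ids = face_ids,
                 features = features, feature_names = feature_names),
            class = "feature_table")
}

#' @export
print.rating_table <- function(x, ...) {
  cat(sprintf("<rating_table> %d faces x %d attributes (Likert %g-%g)\n",
              nrow(x$ratings), ncol(x$ratings), x$likert_min, x$likert_max))
  cat("attributes:", paste(colnames(x$ratings), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> space '%s': %d faces x %d features\n",
              x$space_name, nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' @export
dim.rating_table <- function(x) dim(x$ratings)

#' @export
dim.feature_table <- function(x) dim(x$features)

# Reorder a feature table's rows to match a given face_id ordering.
align_features <- function(features, face_ids) {
  if (!setequal(features$face_ids, face_ids)) {
    missing <- setdiff(face_ids, features$face_ids)
    extra <- setdiff(features$face_ids, face_ids)
    fj_stop("face sets differ between tables",
            if (length(missing)) paste0("; missing from features: ",
                                        paste(utils::head(missing, 5), collapse = ", ")),
            if (length(extra)) paste0("; extra in features: ",
                                      paste(utils::head(extra, 5), collapse = ", ")))
  }
  idx <- match(face_ids, features$face_ids)
  feature_table(features$space_name, features$features[idx, , drop = FALSE],
                face_ids, features$feature_names)
}

#' Read and write rating / feature tables as CSV
#'
#' CSV layout: first column `face_id`, remaining columns numeric, with a
#' header row naming the attributes (rating tables) or features (feature
#' tables). Malformed cells, duplicated face identifiers and missing values
#' are rejected with the offending row/column named in the error.
#'
#' @param path File path.
#' @param likert_min,likert_max Declared scale bounds for rating tables;
#'   out-of-range values produce a warning, not an error.
#' @param space_name Feature-space label to attach on read.
#' @return `read_rating_table()` a [rating_table()]; `read_feature_table()`
#'   a [feature_table()]. The writers return the path, invisibly.
#' @export
read_rating_table <- function(path, likert_min = 1, likert_max = 7) {
  df <- read_face_csv(path)
  rating_table(df$mat, df$face_ids, likert_min = likert_min, likert_max = likert_max)
}

#' @rdname read_rating_table
#' @export
read_feature_table <- function(path, space_name) {
  df <- read_face_csv(path)
  feature_table(space_name, df$mat, df$face_ids)
}

read_face_csv <- function(path) {
  if (!file.exists(path)) fj_stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "face_id") {
    fj_stop("expected a CSV whose first column is 'face_id': ", path)
  }
  face_ids <- as.character(df[[1]])
  if (anyDuplicated(face_ids)) {
    fj_stop("duplicate face_id '", face_ids[duplicated(face_ids)][1], "' in ", path)
  }
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0) {
        fj_stop(sprintf("non-numeric cell at row %d (face '%s'), column '%s' in %s",
                        bad[1], face_ids[bad[1]], names(body)[j], path))
      }
      body[[j]] <- vn
    }
    bad <- which(!is.finite(body[[j]]))
    if (length(bad) > 0) {
      fj_stop(sprintf("missing/non-finite value at row %d (face '%s'), column '%s' in %s",
                      bad[1], face_ids[bad[1]], names(body)[j], path))
    }
  }
  list(face_ids = face_ids, mat = as.matrix(body))
}

#' @rdname read_rating_table
#' @param x A `rating_table` or `feature_table`.
#' @export
write_rating_table <- function(x, path) {
  stopifnot(inherits(x, "rating_table"))
  write_face_csv(x$face_ids, x$ratings, path)
}

#' @rdname read_rating_table
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  write_face_csv(x$face_ids, x$features, path)
}

write_face_csv <- function(face_ids, mat, path) {
  df <- data.frame(face_id = face_ids, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
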
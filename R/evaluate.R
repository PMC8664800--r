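# Out-of-sample scoring: rank-correlation accuracy with bootstrap
# uncertainty, permutation-based chance thresholds and p-values, and
# Benjamini-Hochberg FDR correction across the evaluated family.

#' Spearman rank-order correlation
#'
#' Pearson correlation of average-ranked values (ties receive their average
#' rank). Used as the accuracy metric throughout because test datasets may
#' use different rating scales, making rank order the comparable quantity.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, neither constant.
#' @return The correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) fj_stop("x and y must have equal length")
  if (length(x) < 3L) fj_stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) fj_stop("inputs must be finite")
  if (stats::sd(x) == 0) fj_stop("vector 'x' is constant; rank correlation undefined")
  if (stats::sd(y) == 0) fj_stop("vector 'y' is constant; rank correlation undefined")
  stats::cor(x, y, method = "spearman")
}

#' Bootstrap estimate of prediction accuracy
#'
#' Resamples faces with replacement `n_boot` times and computes the
#' Spearman correlation between resampled predicted and actual ratings.
#' For multi-image datasets, supply `identity_map` (one identity label per
#' face, aligned with the vectors): each iteration first draws one image
#' per identity, then resamples the resulting identities with replacement,
#' so identities with many images do not dominate. Resamples in which
#' either vector is constant are skipped (not scored) and counted.
#'
#' @param predicted,actual Aligned numeric vectors.
#' @param identity_map Optional character vector of identity labels, one
#'   per element of `predicted`. If every identity has a single image the
#'   procedure reduces exactly to plain face resampling.
#' @param n_boot Number of bootstrap iterations.
#' @param seed Integer seed.
#' @return List with `mean_rho`, `boot_sd`, `n_boot`, `n_skipped`, and the
#'   vector of per-iteration correlations `rhos`.
#' @export
bootstrap_accuracy <- function(predicted, actual, identity_map = NULL,
                               n_boot = 1000L, seed = 1L) {
  n <- length(predicted)
  if (length(actual) != n) fj_stop("predicted and actual must have equal length")
  n_boot <- assert_count(n_boot, "n_boot")
  use_identities <- FALSE
  if (!is.null(identity_map)) {
    if (length(identity_map) != n) {
      fj_stop("identity_map must have one identity per face")
    }
    identity_map <- as.character(identity_map)
    images_of <- split(seq_len(n), identity_map)
    # preserve first-appearance order of identities
    images_of <- images_of[unique(identity_map)]
    use_identities <- any(lengths(images_of) > 1L)
  }
  rhos <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      if (use_identities) {
        one_each <- vapply(images_of, function(im) {
          if (length(im) == 1L) im else im[sample.int(length(im), 1L)]
        }, integer(1))
        idx <- one_each[sample.int(length(one_each), replace = TRUE)]
      } else {
        idx <- sample.int(n, replace = TRUE)
      }
      p <- predicted[idx]; a <- actual[idx]
      if (stats::sd(p) == 0 || stats::sd(a) == 0) NA_real_
      else stats::cor(p, a, method = "spearman")
    }, numeric(1))
  })
  n_skipped <- sum(is.na(rhos))
  if (n_skipped == n_boot) fj_stop("all bootstrap resamples were degenerate (constant)")
  list(mean_rho = mean(rhos, na.rm = TRUE),
       boot_sd = stats::sd(rhos[!is.na(rhos)]),
       n_boot = n_boot, n_skipped = n_skipped, rhos = rhos)
}

# All permutations of 1..n (n small), as an n! x n matrix.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Permutation null distribution for a prediction accuracy
#'
#' Shuffles `actual` across faces `n_perm` times, recomputing the Spearman
#' correlation against `predicted` each time, under the null hypothesis of
#' no association between features and judgments. Returns the
#' 95th-percentile chance threshold, the one-sided permutation p-value
#' (plain proportion of null correlations greater than or equal to the
#' observed one; optional add-one smoothing), and the null sample.
#'
#' @param predicted,actual Aligned numeric vectors, neither constant.
#' @param n_perm Number of permutations (>= 100 unless `exhaustive`).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all `n!` permutations instead of sampling
#'   (only for small `n`; overrides `n_perm`).
#' @param smooth Use the smoothed estimate `(b + 1) / (n_perm + 1)` instead
#'   of the plain proportion (default off).
#' @return List with `chance_threshold` (95th percentile of the null),
#'   `p_perm`, `observed_rho`, and `null_sample`.
#' @export
permutation_null <- function(predicted, actual, n_perm = 1000L, seed = 1L,
                             exhaustive = FALSE, smooth = FALSE) {
  obs <- spearman_rho(predicted, actual)
  n <- length(predicted)
  rp <- rank(predicted); rp <- rp - mean(rp)
  ra <- rank(actual);    ra <- ra - mean(ra)
  denom <- sqrt(sum(rp^2) * sum(ra^2))
  if (exhaustive) {
    if (n > 8L) fj_stop("exhaustive enumeration is limited to n <= 8")
    P <- all_permutations(n)
    null_sample <- as.vector((matrix(ra[t(P)], ncol = n, byrow = TRUE) %*% rp) / denom)
  } else {
    n_perm <- assert_count(n_perm, "n_perm", min = 100L)
    M <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
    })
    null_sample <- as.vector(crossprod(matrix(ra[M], n), rp) / denom)
  }
  p <- if (smooth) (sum(null_sample >= obs) + 1) / (length(null_sample) + 1)
       else mean(null_sample >= obs)
  list(chance_threshold = unname(stats::quantile(null_sample, 0.95)),
       p_perm = p, observed_rho = obs, null_sample = null_sample)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values: monotone in p, and elementwise at least p after
#' monotonicity enforcement.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
fdr_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0 | p_values > 1)) {
    fj_stop("p_values must all lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Evaluate fitted models on an out-of-sample test set
#'
#' For each (model attribute, test attribute) pair in the mapping:
#' predicts with the fitted model (negating weights when the pair is an
#' antonym pair), estimates bootstrap accuracy, computes the permutation
#' chance threshold and p-value, then FDR-corrects across the evaluated
#' family at level `alpha`.
#'
#' @param models Named list of `fitted_model` objects (one feature space).
#' @param test_ratings Test-set [rating_table()].
#' @param test_features Test-set [feature_table()] of the models' space.
#' @param attribute_mapping Data frame with columns `model_attribute`,
#'   `test_attribute`, and logical `antonym`. Default: the identity
#'   mapping over attributes present in both models and test ratings.
#' @param n_boot,n_perm Bootstrap and permutation iteration counts.
#' @param alpha FDR significance level (default 0.05).
#' @param seed Integer seed; each pair derives its own seed.
#' @param identity_map Optional identity labels for multi-image test sets
#'   (named by face id, or aligned with the test faces).
#' @param smooth Passed to [permutation_null()].
#' @return A data frame (class `accuracy_results`), one row per pair:
#'   `mean_rho`, `boot_sd`, `chance_threshold`, `p_perm`, `q_fdr`,
#'   `significant`, plus bookkeeping columns.
#' @export
evaluate_models <- function(models, test_ratings, test_features,
                            attribute_mapping = NULL,
                            n_boot = 1000L, n_perm = 1000L, alpha = 0.05,
                            seed = 1L, identity_map = NULL, smooth = FALSE) {
  stopifnot(inherits(test_ratings, "rating_table"),
            inherits(test_features, "feature_table"))
  if (is.null(attribute_mapping)) {
    common <- intersect(names(models), colnames(test_ratings$ratings))
    if (length(common) == 0) fj_stop("no common attributes between models and test ratings")
    attribute_mapping <- data.frame(model_attribute = common,
                                    test_attribute = common,
                                    antonym = FALSE)
  }
  stopifnot(all(c("model_attribute", "test_attribute", "antonym") %in%
                  names(attribute_mapping)))
  test_features <- align_features(test_features, test_ratings$face_ids)
  id_vec <- NULL
  if (!is.null(identity_map)) {
    id_vec <- if (!is.null(names(identity_map))) {
      unname(identity_map[test_ratings$face_ids])
    } else identity_map
  }
  rows <- lapply(seq_len(nrow(attribute_mapping)), function(i) {
    ma <- attribute_mapping$model_attribute[i]
    ta <- attribute_mapping$test_attribute[i]
    anti <- isTRUE(attribute_mapping$antonym[i])
    if (!ma %in% names(models)) fj_stop("no fitted model for attribute '", ma, "'")
    if (!ta %in% colnames(test_ratings$ratings)) {
      fj_stop("attribute '", ta, "' not present in test ratings")
    }
    preds <- predict(models[[ma]], test_features, flip_sign = anti)
    actual <- test_ratings$ratings[, ta]
    pair_seed <- derive_seed(seed, paste0(ma, "->", ta))
    boot <- bootstrap_accuracy(preds, actual, identity_map = id_vec,
                               n_boot = n_boot, seed = pair_seed)
    perm <- permutation_null(preds, actual, n_perm = n_perm,
                             seed = derive_seed(pair_seed, "perm"),
                             smooth = smooth)
    data.frame(model_attribute = ma, test_attribute = ta, antonym = anti,
               mean_rho = boot$mean_rho, boot_sd = boot$boot_sd,
               chance_threshold = perm$chance_threshold,
               p_perm = perm$p_perm, observed_rho = perm$observed_rho,
               n_boot = n_boot, n_perm = n_perm,
               n_skipped = boot$n_skipped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_fdr <- fdr_adjust(out$p_perm)
  out$significant <- out$q_fdr < alpha
  class(out) <- c("accuracy_results", "data.frame")
  out
}
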
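# Synthetic-data generator. Emulates the statistical structure the analysis
# modules assume: a small number of latent psychological dimensions that
# induce correlated attribute ratings; several feature spaces carrying
# controlled shared/unique portions of that latent signal; out-of-sample
# test sets with disjoint faces and fresh rater noise; multi-image
# "ambient" sets; and a global image-style perturbation that contaminates
# feature spaces in proportion to their style sensitivity.

#' Specify one synthetic feature space
#'
#' Each feature space is generated as a linear image of the latent
#' psychological dimensions (the portion that carries rating-relevant
#' signal), plus a linear image of space-specific latent factors that are
#' unrelated to the ratings, plus i.i.d. measurement noise. Per feature,
#' the rating-latent channel has variance `signal_fraction_shared`, the
#' space-specific channel `signal_fraction_unique`, and any remainder of
#' the unit "face signal" budget is folded into the noise, on top of
#' `noise_sd^2`.
#'
#' @param name Feature-space label.
#' @param n_features Number of features.
#' @param signal_fraction_shared Fraction (0-1) of per-feature face-signal
#'   variance driven by the rating latents (shareable with other spaces
#'   exposed to the same latents).
#' @param signal_fraction_unique Fraction (0-1) driven by space-specific
#'   latent factors with no bearing on the ratings.
#' @param noise_sd Additional i.i.d. noise standard deviation (feature units).
#' @param style_sensitivity In `[0, 1]`: how strongly a dataset-level style
#'   perturbation contaminates this space (see
#'   [apply_style_perturbation()]). 0 means fully style-invariant.
#' @param latent_subset Integer indices of the rating latents this space is
#'   exposed to (default all). Exposing two spaces to overlapping but
#'   unequal subsets creates ground-truth unique and shared explained
#'   rating variance for variance-partitioning checks.
#' @return An object of class `feature_space_spec`.
#' @export
feature_space_spec <- function(name, n_features,
                               signal_fraction_shared = 0.6,
                               signal_fraction_unique = 0.2,
                               noise_sd = 0.1,
                               style_sensitivity = 0,
                               latent_subset = NULL) {
  n_features <- assert_count(n_features, "n_features")
  fs <- assert_proportion(signal_fraction_shared, "signal_fraction_shared")
  fu <- assert_proportion(signal_fraction_unique, "signal_fraction_unique")
  if (fs + fu > 1 + 1e-12) {
    fj_stop("signal_fraction_shared + signal_fraction_unique must be <= 1")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) fj_stop("noise_sd must be >= 0")
  ss <- assert_proportion(style_sensitivity, "style_sensitivity")
  if (!is.null(latent_subset)) {
    latent_subset <- vapply(latent_subset, assert_count, integer(1), name = "latent_subset")
    if (anyDuplicated(latent_subset)) fj_stop("latent_subset has duplicates")
  }
  structure(list(name = as.character(name), n_features = n_features,
                 signal_fraction_shared = fs, signal_fraction_unique = fu,
                 noise_sd = as.numeric(noise_sd), style_sensitivity = ss,
                 latent_subset = latent_subset),
            class = "feature_space_spec")
}

#' Configure a synthetic world of faces, ratings and feature spaces
#'
#' The generator encodes the empirical regularity that a handful of latent
#' psychological dimensions (typically 2-4) account for most of the
#' variance in social judgments: every attribute's mean rating is an affine
#' map of a K-dimensional standard-normal latent score, rescaled into the
#' Likert range, plus per-face residual noise representing what remains
#' after averaging over raters.
#'
#' @param n_latent K, the number of latent psychological dimensions
#'   (at least 2, at most `n_attributes`).
#' @param n_train_faces,n_test_faces Faces (identities) in the training set
#'   and in each test set.
#' @param n_attributes Number of rated social attributes.
#' @param attribute_loadings `n_attributes x n_latent` matrix of loadings;
#'   rows are normalized to unit length internally, so the cosine between
#'   two rows is the designed noiseless correlation between those
#'   attributes' ratings. Must have full column rank. Default: random
#'   loadings (seeded).
#' @param rating_noise_sd Rater-level noise SD in Likert units; divided by
#'   `sqrt(n_raters)` before being added to each per-face mean rating
#'   (rater averaging is simulated analytically).
#' @param n_raters Number of raters averaged per face.
#' @param likert_min,likert_max Rating scale bounds; generated means are
#'   clipped into this range after noise.
#' @param feature_space_specs List of [feature_space_spec()] objects.
#' @param images_per_identity 1 for portrait sets; >1 makes each test set an
#'   "ambient" set with several images per identity (same identity latents,
#'   fresh image-level feature noise, fresh per-image rater noise).
#' @param style_perturbation_sd Scale (feature units) of the dataset-level
#'   style perturbation used by [apply_style_perturbation()].
#' @param n_test_sets Number of independent out-of-sample test sets.
#' @param seed Integer seed; identical config + seed reproduces the world
#'   bit-for-bit.
#' @return An object of class `synthetic_world_config`.
#' @export
synthetic_world_config <- function(n_latent = 2L,
                                   n_train_faces = 183L,
                                   n_test_faces = 60L,
                                   n_attributes = 14L,
                                   attribute_loadings = NULL,
                                   rating_noise_sd = 0.65,
                                   n_raters = 1L,
                                   likert_min = 1,
                                   likert_max = 7,
                                   feature_space_specs = list(
                                     feature_space_spec("identity-like", 32L,
                                                        signal_fraction_shared = 0.7,
                                                        signal_fraction_unique = 0.2,
                                                        noise_sd = 0.1,
                                                        style_sensitivity = 0.1),
                                     feature_space_spec("object-like", 26L,
                                                        signal_fraction_shared = 0.45,
                                                        signal_fraction_unique = 0.35,
                                                        noise_sd = 0.2,
                                                        style_sensitivity = 0.9),
                                     feature_space_spec("geometry-like", 30L,
                                                        signal_fraction_shared = 0.3,
                                                        signal_fraction_unique = 0.4,
                                                        noise_sd = 0.3,
                                                        style_sensitivity = 0.2)),
                                   images_per_identity = 1L,
                                   style_perturbation_sd = 1,
                                   n_test_sets = 1L,
                                   seed = 1L) {
  K <- assert_count(n_latent, "n_latent")
  n_attributes <- assert_count(n_attributes, "n_attributes")
  if (K < 2L || K > n_attributes) {
    fj_stop("n_latent must satisfy 2 <= n_latent <= n_attributes")
  }
  n_train_faces <- assert_count(n_train_faces, "n_train_faces", min = 2L)
  n_test_faces <- assert_count(n_test_faces, "n_test_faces", min = 2L)
  n_raters <- assert_count(n_raters, "n_raters")
  images_per_identity <- assert_count(images_per_identity, "images_per_identity")
  n_test_sets <- assert_count(n_test_sets, "n_test_sets")
  seed <- assert_count(seed, "seed", min = 0L)
  if (!is.numeric(rating_noise_sd) || rating_noise_sd < 0) {
    fj_stop("rating_noise_sd must be >= 0")
  }
  if (!is.numeric(style_perturbation_sd) || style_perturbation_sd < 0) {
    fj_stop("style_perturbation_sd must be >= 0")
  }
  if (likert_max <= likert_min) fj_stop("likert_max must exceed likert_min")
  if (is.null(attribute_loadings)) {
    attribute_loadings <- withr::with_seed(derive_seed(seed, "loadings"), {
      matrix(stats::rnorm(n_attributes * K), n_attributes, K)
    })
  }
  attribute_loadings <- as.matrix(attribute_loadings)
  if (!all(dim(attribute_loadings) == c(n_attributes, K))) {
    fj_stop("attribute_loadings must be n_attributes x n_latent")
  }
  if (qr(attribute_loadings)$rank < K) {
    fj_stop("attribute_loadings is rank-deficient: the ", K,
            " latent dimensions must be identifiable (full column rank)")
  }
  if (!is.list(feature_space_specs) ||
      !all(vapply(feature_space_specs, inherits, logical(1), "feature_space_spec"))) {
    fj_stop("feature_space_specs must be a list of feature_space_spec objects")
  }
  nms <- vapply(feature_space_specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) fj_stop("feature space names must be unique")
  for (sp in feature_space_specs) {
    if (!is.null(sp$latent_subset) && any(sp$latent_subset > K)) {
      fj_stop("latent_subset for space '", sp$name, "' exceeds n_latent")
    }
  }
  if (is.null(rownames(attribute_loadings))) {
    rownames(attribute_loadings) <- sprintf("attr%02d", seq_len(n_attributes))
  }
  structure(list(n_latent = K, n_train_faces = n_train_faces,
                 n_test_faces = n_test_faces, n_attributes = n_attributes,
                 attribute_loadings = attribute_loadings,
                 rating_noise_sd = as.numeric(rating_noise_sd),
                 n_raters = n_raters, likert_min = likert_min,
                 likert_max = likert_max,
                 feature_space_specs = feature_space_specs,
                 images_per_identity = images_per_identity,
                 style_perturbation_sd = as.numeric(style_perturbation_sd),
                 n_test_sets = n_test_sets, seed = seed),
            class = "synthetic_world_config")
}

#' Generate a synthetic world
#'
#' Draws latent scores i.i.d. standard normal per face; maps them to mean
#' attribute ratings (unit-signal-SD affine map into the Likert range, plus
#' noise of SD `rating_noise_sd / sqrt(n_raters)`, then clipping) and to
#' each feature space (fixed linear maps shared between training and test
#' sets, so fitted weights are transferable). Test-set faces are disjoint
#' from training faces and their ratings use fresh noise (independent
#' raters). The population-optimal linear weights of every attribute in
#' every space are recorded for parameter-recovery checks.
#'
#' @param config A [synthetic_world_config()].
#' @return An object of class `synthetic_world` with elements `train`
#'   (list: `ratings`, `features` named by space, `latent_scores`),
#'   `test_sets` (list of the same shape, plus `identity_map` for ambient
#'   sets), `true_weights` (space -> features x attributes matrix) and
#'   `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "synthetic_world_config"))
  K <- config$n_latent
  L <- config$attribute_loadings
  Ln <- L / sqrt(rowSums(L^2))          # unit rows: cosine = designed correlation
  spread <- (config$likert_max - config$likert_min) / 6
  mid <- (config$likert_max + config$likert_min) / 2
  noise_sd <- config$rating_noise_sd / sqrt(config$n_raters)
  attrs <- rownames(L)

  withr::with_seed(config$seed, {
    maps <- lapply(config$feature_space_specs, function(sp) {
      sub <- sp$latent_subset %||% seq_len(K)
      p <- sp$n_features
      A <- matrix(stats::rnorm(length(sub) * p), length(sub), p)
      A <- scale_columns(A, sqrt(sp$signal_fraction_shared))
      B <- matrix(stats::rnorm(K * p), K, p)
      B <- scale_columns(B, sqrt(sp$signal_fraction_unique))
      eff_noise_sd <- sqrt(sp$noise_sd^2 +
                             max(0, 1 - sp$signal_fraction_shared - sp$signal_fraction_unique))
      list(spec = sp, subset = sub, A = A, B = B, eff_noise_sd = eff_noise_sd)
    })
    names(maps) <- vapply(maps, function(m) m$spec$name, character(1))

    gen_dataset <- function(n, prefix, m_images) {
      ids <- sprintf("%s_%04d", prefix, seq_len(n))
      Z <- matrix(stats::rnorm(n * K), n, K)
      signal <- mid + spread * (Z %*% t(Ln))
      expand <- rep(seq_len(n), each = m_images)
      face_ids <- if (m_images == 1L) ids else {
        paste0(ids[expand], sprintf("_img%02d", rep(seq_len(m_images), times = n)))
      }
      n_img <- length(face_ids)
      R <- signal[expand, , drop = FALSE] +
        matrix(stats::rnorm(n_img * nrow(Ln), sd = noise_sd), n_img)
      R <- pmin(pmax(R, config$likert_min), config$likert_max)
      colnames(R) <- attrs
      feats <- lapply(maps, function(mp) {
        p <- mp$spec$n_features
        U <- matrix(stats::rnorm(n * K), n, K)
        ident_part <- Z[, mp$subset, drop = FALSE] %*% mp$A + U %*% mp$B
        X <- ident_part[expand, , drop = FALSE] +
          matrix(stats::rnorm(n_img * p, sd = mp$eff_noise_sd), n_img)
        colnames(X) <- sprintf("%s_f%03d", gsub("[^A-Za-z0-9]", "", mp$spec$name), seq_len(p))
        feature_table(mp$spec$name, X, face_ids)
      })
      identity_map <- if (m_images > 1L) stats::setNames(ids[expand], face_ids) else NULL
      list(ratings = rating_table(R, face_ids, config$likert_min, config$likert_max),
           features = feats, identity_map = identity_map, latent_scores = Z)
    }

    train <- gen_dataset(config$n_train_faces, "train", 1L)
    test_sets <- lapply(seq_len(config$n_test_sets), function(i) {
      gen_dataset(config$n_test_faces, sprintf("test%d", i), config$images_per_identity)
    })

    true_weights <- lapply(maps, function(mp) {
      Sigma <- crossprod(mp$A) + crossprod(mp$B) +
        diag(mp$eff_noise_sd^2, mp$spec$n_features)
      Cxy <- spread * t(mp$A) %*% t(Ln[, mp$subset, drop = FALSE])
      W <- solve(Sigma, Cxy)
      dimnames(W) <- list(colnames(train$features[[mp$spec$name]]$features), attrs)
      W
    })

    structure(list(train = train, test_sets = test_sets,
                   true_weights = true_weights, config = config),
              class = "synthetic_world")
  })
}

scale_columns <- function(M, target_norm) {
  norms <- sqrt(colSums(M^2))
  norms[norms == 0] <- 1
  sweep(M, 2, target_norm / norms, `*`)
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> K=%d latents, %d attributes, %d train faces, %d test set(s)\n",
              x$config$n_latent, x$config$n_attributes,
              x$config$n_train_faces, length(x$test_sets)))
  cat("feature spaces:", paste(names(x$true_weights), collapse = ", "), "\n")
  invisible(x)
}

#' Apply a dataset-level image-style perturbation to a feature table
#'
#' Emulates a global change of image style (e.g. grayscale conversion or
#' luminance equalization applied to every photo of a test set) at the
#' feature level: every face is displaced along one shared random "style"
#' direction, by a per-face random amount, scaled by the space's style
#' sensitivity. A style-invariant space (`style_sensitivity = 0`) is
#' returned untouched; a style-sensitive space acquires rank-one
#' contamination that degrades downstream prediction accuracy.
#'
#' @param features A [feature_table()].
#' @param spec The [feature_space_spec()] of the same space (names must
#'   match); supplies `style_sensitivity`.
#' @param seed Integer seed; the same seed reproduces the same style event.
#' @param style_perturbation_sd Scale of the perturbation in feature units.
#' @return A new `feature_table`; the input is not modified and face
#'   identifiers are preserved.
#' @export
apply_style_perturbation <- function(features, spec, seed,
                                     style_perturbation_sd = 1) {
  stopifnot(inherits(features, "feature_table"),
            inherits(spec, "feature_space_spec"))
  if (!identical(features$space_name, spec$name)) {
    fj_stop("feature space mismatch: table is '", features$space_name,
            "' but spec is '", spec$name, "'")
  }
  if (spec$style_sensitivity == 0 || style_perturbation_sd == 0) {
    return(features)
  }
  p <- ncol(features$features)
  n <- nrow(features$features)
  withr::with_seed(seed, {
    d <- stats::rnorm(p)
    d <- d / sqrt(sum(d^2))
    g <- stats::rnorm(n)
  })
  X <- features$features +
    spec$style_sensitivity * style_perturbation_sd * outer(g, d)
  feature_table(features$space_name, X, features$face_ids,
                features$feature_names)
}

#' Read and write a synthetic world configuration as YAML
#'
#' @param config A [synthetic_world_config()].
#' @param path YAML file path.
#' @return The config (reader) or the path, invisibly (writer).
#' @export
write_world_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_world_config"))
  out <- unclass(config)
  out$attribute_loadings <- apply(config$attribute_loadings, 1, as.numeric,
                                  simplify = FALSE)
  names(out$attribute_loadings) <- rownames(config$attribute_loadings)
  out$feature_space_specs <- lapply(config$feature_space_specs, unclass)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_world_config
#' @export
read_world_config <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw$feature_space_specs, function(s) do.call(feature_space_spec, s))
  loadings <- do.call(rbind, raw$attribute_loadings)
  rownames(loadings) <- names(raw$attribute_loadings)
  args <- raw[setdiff(names(raw), c("feature_space_specs", "attribute_loadings"))]
  args$feature_space_specs <- specs
  args$attribute_loadings <- loadings
  do.call(synthetic_world_config, args)
}
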
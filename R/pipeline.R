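# End-to-end orchestration: generate (or load) data, extract geometry
# features, fit per-attribute models per feature space, evaluate
# out-of-sample, partition variance between space pairs, audit
# cross-prediction specificity, and write every artifact plus a manifest
# with seeds and checksums. Stage seeds are derived deterministically from
# the global seed and the stage name, so a run is reproducible from the
# config alone. Test-set ratings are only touched after all models are
# fitted.

#' Build a pipeline run configuration
#'
#' @param world [synthetic_world_config()] describing the synthetic data
#'   (or NULL to supply `rating_csv` / `feature_csvs` paths).
#' @param fit [fit_config()] used for all model fitting.
#' @param n_boot,n_perm Evaluation iteration counts.
#' @param alpha FDR level.
#' @param partition_spaces Character vector of length 2: which spaces to
#'   variance-partition (default: the first two of the world).
#' @param partition_attributes Attributes to partition (default: all).
#' @param controls Control attributes for the semi-partial analysis
#'   (default: every fitted attribute).
#' @param cross_prediction_space Space used for the specificity audit
#'   (default: the first).
#' @param n_landmark_faces If > 0, also generate landmark fixtures and a
#'   facial-geometry feature table as artifacts.
#' @param output_dir Where artifacts are written.
#' @param seed Global integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(world = synthetic_world_config(),
                       fit = fit_config(n_cv_iterations = 200L),
                       n_boot = 1000L, n_perm = 1000L, alpha = 0.05,
                       partition_spaces = NULL,
                       partition_attributes = NULL,
                       controls = NULL,
                       cross_prediction_space = NULL,
                       n_landmark_faces = 0L,
                       output_dir = "facejudge_run",
                       seed = 1L) {
  stopifnot(inherits(world, "synthetic_world_config"),
            inherits(fit, "fit_config"))
  seed <- assert_count(seed, "seed", min = 0L)
  structure(list(world = world, fit = fit,
                 n_boot = assert_count(n_boot, "n_boot"),
                 n_perm = assert_count(n_perm, "n_perm"),
                 alpha = alpha,
                 partition_spaces = partition_spaces,
                 partition_attributes = partition_attributes,
                 controls = controls,
                 cross_prediction_space = cross_prediction_space,
                 n_landmark_faces = assert_count(n_landmark_faces,
                                                 "n_landmark_faces", min = 0L),
                 output_dir = output_dir, seed = seed),
            class = "run_config")
}

#' A small, fast demonstration configuration
#'
#' Scaled for interactive use (hundreds of cross-validation and resampling
#' iterations rather than thousands); `paper_scale = TRUE` restores
#' full-scale iteration counts (2000 cross-validation splits, 10000
#' bootstrap and permutation iterations).
#'
#' @param seed Global seed.
#' @param paper_scale Use full-scale iteration counts.
#' @return A [run_config()].
#' @export
demo_run_config <- function(seed = 1L, paper_scale = FALSE) {
  world <- synthetic_world_config(
    n_latent = 2L, n_train_faces = 80L, n_test_faces = 50L,
    n_attributes = 5L, rating_noise_sd = 0.5, seed = derive_seed(seed, "world"),
    feature_space_specs = list(
      feature_space_spec("identity-like", 16L, signal_fraction_shared = 0.7,
                         signal_fraction_unique = 0.2, noise_sd = 0.1,
                         style_sensitivity = 0.1),
      feature_space_spec("object-like", 12L, signal_fraction_shared = 0.45,
                         signal_fraction_unique = 0.35, noise_sd = 0.2,
                         style_sensitivity = 0.9)))
  run_config(world = world,
             fit = fit_config(lambda_grid = 10^seq(0, 5, length.out = 10),
                              n_cv_iterations = if (paper_scale) 2000L else 60L,
                              seed = derive_seed(seed, "fit")),
             n_boot = if (paper_scale) 10000L else 200L,
             n_perm = if (paper_scale) 10000L else 200L,
             partition_attributes = "attr01",
             controls = "attr01",
             n_landmark_faces = 10L,
             seed = seed)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — generate, geometry, fit,
#' evaluate, partition, cross-predict, summarize — writing every artifact
#' (CSV/JSON) under `config$output_dir` and returning a manifest with the
#' derived stage seeds and MD5 checksums of all outputs. Re-running with
#' an identical config reproduces identical numeric content.
#'
#' @param config A [run_config()].
#' @param output_dir Overrides `config$output_dir`.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, output_dir = config$output_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(world = config$world$seed,
                fit = config$fit$seed,
                evaluate = derive_seed(config$seed, "evaluate"),
                partition = derive_seed(config$seed, "partition"),
                crosspredict = derive_seed(config$seed, "crosspredict"),
                landmarks = derive_seed(config$seed, "landmarks"))
  log_msg <- function(...) message("[facejudge] ", sprintf(...))

  # -- generate ------------------------------------------------------------
  log_msg("generate: synthetic world (seed %d)", seeds$world)
  world <- generate_world(config$world)
  spaces <- names(world$true_weights)
  write_world_config(config$world, file.path(output_dir, "world_config.yaml"))
  write_rating_table(world$train$ratings, file.path(output_dir, "train_ratings.csv"))
  for (s in spaces) {
    write_feature_table(world$train$features[[s]],
                        file.path(output_dir, sprintf("train_features_%s.csv", slug(s))))
  }
  test <- world$test_sets[[1]]
  for (s in spaces) {
    write_feature_table(test$features[[s]],
                        file.path(output_dir, sprintf("test1_features_%s.csv", slug(s))))
  }

  # -- geometry fixtures ---------------------------------------------------
  if (config$n_landmark_faces > 0) {
    log_msg("geometry: %d landmark faces", config$n_landmark_faces)
    lms <- generate_landmarks(config$n_landmark_faces, seed = seeds$landmarks)
    write_landmarks_json(lms, file.path(output_dir, "landmarks.json"))
    write_feature_table(batch_geometry_table(lms),
                        file.path(output_dir, "geometry_features.csv"))
  }

  # -- fit (test-set ratings untouched until this completes) ---------------
  models <- lapply(spaces, function(s) {
    log_msg("fit: %d attributes on '%s'", config$world$n_attributes, s)
    fit_all_attributes(world$train$features[[s]], world$train$ratings, config$fit)
  })
  names(models) <- spaces
  for (s in spaces) {
    for (m in models[[s]]) {
      write_fitted_model(m, file.path(output_dir,
                                      sprintf("model_%s_%s.json", slug(s), m$attribute)))
    }
  }

  # -- evaluate ------------------------------------------------------------
  write_rating_table(test$ratings, file.path(output_dir, "test1_ratings.csv"))
  eval_rows <- lapply(spaces, function(s) {
    log_msg("evaluate: '%s' on test set 1", s)
    res <- evaluate_models(models[[s]], test$ratings, test$features[[s]],
                           n_boot = config$n_boot, n_perm = config$n_perm,
                           alpha = config$alpha,
                           seed = derive_seed(seeds$evaluate, s),
                           identity_map = test$identity_map)
    res$space <- s
    res
  })
  evaluation <- do.call(rbind, eval_rows)
  utils::write.csv(evaluation, file.path(output_dir, "evaluation.csv"),
                   row.names = FALSE)

  # -- partition -----------------------------------------------------------
  partition <- NULL
  pair <- config$partition_spaces %||% utils::head(spaces, 2)
  if (length(pair) == 2 && all(pair %in% spaces)) {
    attrs <- config$partition_attributes %||% colnames(world$train$ratings$ratings)
    log_msg("partition: %s vs %s (%d attribute(s))", pair[1], pair[2], length(attrs))
    parts <- lapply(attrs, function(a) {
      bootstrap_partition(world$train$ratings,
                          world$train$features[[pair[1]]],
                          world$train$features[[pair[2]]],
                          test$ratings, test$features[[pair[1]]],
                          test$features[[pair[2]]],
                          a, config$fit,
                          n_boot = max(100L, config$n_boot),
                          seed = derive_seed(seeds$partition, a))
    })
    partition <- partition_table(parts, alpha = config$alpha)
    utils::write.csv(partition, file.path(output_dir, "variance_partition.csv"),
                     row.names = FALSE)
  }

  # -- cross-predict -------------------------------------------------------
  cp_space <- config$cross_prediction_space %||% spaces[1]
  log_msg("crosspredict: specificity audit on '%s'", cp_space)
  cpm <- cross_prediction_matrix(models[[cp_space]], test$ratings,
                                 test$features[[cp_space]],
                                 n_boot = config$n_boot, n_perm = config$n_perm,
                                 alpha = config$alpha, seed = seeds$crosspredict,
                                 identity_map = test$identity_map)
  write_cross_prediction_csv(cpm, file.path(output_dir, "cross_prediction.csv"))
  controls <- config$controls %||% names(models[[cp_space]])
  residuals <- lapply(controls, function(ctrl) {
    semi_partial_residual_matrix(models[[cp_space]], test$ratings,
                                 test$features[[cp_space]], ctrl,
                                 n_boot = config$n_boot, n_perm = config$n_perm,
                                 alpha = config$alpha, seed = seeds$crosspredict,
                                 identity_map = test$identity_map)
  })
  for (res in residuals) {
    write_cross_prediction_csv(res, file.path(output_dir,
                                              sprintf("residual_cross_prediction_%s.csv",
                                                      res$control_attribute)))
  }
  summaries <- cross_prediction_summaries(cpm, residuals)
  jsonlite::write_json(summaries, file.path(output_dir, "cross_prediction_summaries.json"),
                       digits = NA, dataframe = "rows")

  # -- manifest ------------------------------------------------------------
  files <- setdiff(list.files(output_dir), "manifest.json")
  checksums <- as.list(tools::md5sum(file.path(output_dir, files)))
  names(checksums) <- files
  manifest <- list(package_version = as.character(utils::packageVersion("facejudge")),
                   global_seed = config$seed, stage_seeds = seeds,
                   spaces = spaces, n_attributes = config$world$n_attributes,
                   outputs = checksums)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  log_msg("done: %d artifacts in %s", length(files) + 1L, output_dir)
  invisible(manifest)
}

slug <- function(x) gsub("[^A-Za-z0-9]+", "-", x)
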
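# Cross-prediction specificity matrix, semi-partial residual analysis,
# and dataset-level summaries.

fitted_world <- function(seed, L = NULL, n_attributes = 3L, n_train = 120L,
                         n_test = 80L, noise = 0.4) {
  cfg <- synthetic_world_config(
    n_latent = 2L, n_train_faces = n_train, n_test_faces = n_test,
    n_attributes = if (is.null(L)) n_attributes else nrow(L),
    attribute_loadings = L, rating_noise_sd = noise,
    feature_space_specs = list(
      feature_space_spec("S", 12L, signal_fraction_shared = 0.8,
                         signal_fraction_unique = 0.1, noise_sd = 0.05)),
    seed = seed)
  w <- generate_world(cfg)
  models <- fit_all_attributes(w$train$features$S, w$train$ratings, fast_fit(seed))
  list(world = w, models = models, test = w$test_sets[[1]])
}

test_that("duplicated target rows equal the self-prediction row exactly", {
  fw <- fitted_world(1)
  ts <- fw$test
  R <- cbind(ts$ratings$ratings, attr01_copy = ts$ratings$ratings[, "attr01"])
  dup_ratings <- rating_table(R, ts$ratings$face_ids)
  cpm <- cross_prediction_matrix(fw$models, dup_ratings, ts$features$S,
                                 n_boot = 150, n_perm = 150, seed = 2)
  cells <- cpm$cells
  orig <- cells[cells$test_attribute == "attr01", ]
  copy <- cells[cells$test_attribute == "attr01_copy", ]
  expect_equal(copy$observed_rho, orig$observed_rho, tolerance = 1e-12)
})

test_that("the diagonal agrees with the evaluation module at the same seed", {
  fw <- fitted_world(3)
  ts <- fw$test
  seed <- 11
  cpm <- cross_prediction_matrix(fw$models, ts$ratings, ts$features$S,
                                 n_boot = 150, n_perm = 150, seed = seed)
  for (a in names(fw$models)) {
    cell <- cpm$cells[cpm$cells$test_attribute == a &
                        cpm$cells$model_attribute == a, ]
    boot <- bootstrap_accuracy(predict(fw$models[[a]], ts$features$S),
                               ts$ratings$ratings[, a], n_boot = 150,
                               seed = derive_seed(seed, paste0(a, "|", a)))
    expect_equal(cell$mean_rho, boot$mean_rho, tolerance = 1e-12)
  }
})

test_that("independent attributes yield no significant off-diagonal cells", {
  L <- rbind(a1 = c(1, 0), a2 = c(0, 1))
  frac <- vapply(1:10, function(s) {
    fw <- fitted_world(100 + s, L = L, noise = 0.3)
    cpm <- cross_prediction_matrix(fw$models, fw$test$ratings, fw$test$features$S,
                                   n_boot = 100, n_perm = 200, seed = s)
    off <- cpm$cells[cpm$cells$test_attribute != cpm$cells$model_attribute, ]
    mean(off$significant)
  }, numeric(1))
  expect_lte(mean(frac), 0.1)
})

test_that("off-diagonal accuracy interpolates between self-prediction accuracies", {
  # two attributes share one latent with loadings 1.0 and 0.8
  L <- rbind(a1 = c(1, 0), a2 = c(0.8, 0.6))
  diffs <- t(vapply(1:10, function(s) {
    fw <- fitted_world(200 + s, L = L, noise = 0.3)
    cpm <- cross_prediction_matrix(fw$models, fw$test$ratings, fw$test$features$S,
                                   n_boot = 100, n_perm = 100, seed = s)
    cells <- cpm$cells
    rho <- function(t, m) cells$observed_rho[cells$test_attribute == t &
                                               cells$model_attribute == m]
    c(off = rho("a1", "a2"), self = min(rho("a1", "a1"), rho("a2", "a2")))
  }, numeric(2)))
  expect_gt(mean(diffs[, "off"]), 0)
  expect_lt(mean(diffs[, "off"]), mean(diffs[, "self"]))
})

test_that("an orthogonal control is a no-op for residual cross-prediction", {
  fw <- fitted_world(5)
  ts <- fw$test
  # make a control model whose predictions are exactly orthogonal to the
  # other models' predictions: zero weights (constant predictions)
  zero_ctrl <- fw$models$attr01
  zero_ctrl$weights[] <- 0
  models <- fw$models
  models$ctrl <- zero_ctrl
  models$ctrl$attribute <- "ctrl"
  res <- semi_partial_residual_matrix(models, ts$ratings, ts$features$S, "ctrl",
                                      n_boot = 100, n_perm = 150, seed = 4)
  raw <- cross_prediction_matrix(fw$models, ts$ratings, ts$features$S,
                                 n_boot = 100, n_perm = 150, seed = 4)
  merged <- merge(res$cells, raw$cells,
                  by = c("test_attribute", "model_attribute"))
  expect_gt(nrow(merged), 0)
  expect_equal(merged$observed_rho.x, merged$observed_rho.y, tolerance = 1e-10)
  expect_false("ctrl" %in% res$cells$model_attribute)
})

test_that("a model controlled by itself is flagged degenerate, not scored", {
  fw <- fitted_world(6)
  ts <- fw$test
  models <- fw$models
  models$twin <- models$attr01          # identical predictions to attr01
  models$twin$attribute <- "twin"
  res <- semi_partial_residual_matrix(models, ts$ratings, ts$features$S, "attr01",
                                      n_boot = 100, n_perm = 150, seed = 7)
  twin_cells <- res$cells[res$cells$model_attribute == "twin", ]
  expect_true(all(twin_cells$degenerate))
  expect_true(all(is.na(twin_cells$mean_rho)))
  other <- res$cells[res$cells$model_attribute != "twin", ]
  expect_false(any(other$degenerate))
})

test_that("summaries match a naive loop over cells", {
  fw <- fitted_world(8)
  ts <- fw$test
  cpm <- cross_prediction_matrix(fw$models, ts$ratings, ts$features$S,
                                 n_boot = 100, n_perm = 150, seed = 9)
  res <- lapply(names(fw$models), function(ctrl) {
    semi_partial_residual_matrix(fw$models, ts$ratings, ts$features$S, ctrl,
                                 n_boot = 100, n_perm = 150, seed = 9)
  })
  tab <- cross_prediction_summaries(cpm, res)
  expect_identical(tab$control[1], "none")
  loop_mean <- function(cells) {
    vals <- c(); row_best <- list()
    for (i in seq_len(nrow(cells))) {
      r <- cells[i, ]
      if (r$degenerate || r$test_attribute == r$model_attribute) next
      vals <- c(vals, abs(r$mean_rho))
      ta <- r$test_attribute
      row_best[[ta]] <- max(row_best[[ta]] %||% -Inf, abs(r$mean_rho))
    }
    c(mean(vals), mean(unlist(row_best)))
  }
  lm0 <- loop_mean(cpm$cells)
  expect_equal(tab$mean_abs_rho[1], lm0[1], tolerance = 1e-12)
  expect_equal(tab$mean_row_max_abs_rho[1], lm0[2], tolerance = 1e-12)
  for (j in seq_along(res)) {
    lmj <- loop_mean(res[[j]]$cells)
    expect_equal(tab$mean_abs_rho[j + 1], lmj[1], tolerance = 1e-12)
  }
  expect_equal(sum(tab$most_impactful), 1L)
  expect_false(tab$most_impactful[1])
})

test_that("specificity rises with generative inter-attribute correlation", {
  corr_of <- function(r, s) {
    L <- rbind(a1 = c(1, 0), a2 = c(r, sqrt(1 - r^2)))
    fw <- fitted_world(300 + s, L = L, noise = 0.3)
    cpm <- cross_prediction_matrix(fw$models, fw$test$ratings, fw$test$features$S,
                                   n_boot = 80, n_perm = 150, seed = s)
    off <- cpm$cells[cpm$cells$test_attribute != cpm$cells$model_attribute, ]
    mean(off$significant)
  }
  grid <- c(0, 0.5, 0.9)
  frac <- vapply(grid, function(r) mean(vapply(1:8, function(s) corr_of(r, s),
                                               numeric(1))), numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_lte(frac[1], 0.15)
  expect_gte(frac[3], 0.8)
})
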
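# Synthetic world generator: determinism, latent structure, disjointness,
# correlation control, style perturbation semantics, landmark fixtures.

test_that("identical config and seed reproduce the world bit-for-bit", {
  cfg <- synthetic_world_config(n_train_faces = 40, n_test_faces = 20,
                                n_attributes = 4, seed = 17)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$train$ratings$ratings, w2$train$ratings$ratings)
  expect_identical(w1$train$features[[1]]$features, w2$train$features[[1]]$features)
  expect_identical(w1$test_sets[[1]]$ratings$ratings, w2$test_sets[[1]]$ratings$ratings)
  expect_identical(w1$true_weights, w2$true_weights)
})

test_that("train and test face identifiers are disjoint and ratings in range", {
  cfg <- synthetic_world_config(n_train_faces = 30, n_test_faces = 25,
                                n_attributes = 3, n_test_sets = 2, seed = 3)
  w <- generate_world(cfg)
  for (ts in w$test_sets) {
    expect_length(intersect(w$train$ratings$face_ids, ts$ratings$face_ids), 0)
  }
  expect_length(intersect(w$test_sets[[1]]$ratings$face_ids,
                          w$test_sets[[2]]$ratings$face_ids), 0)
  r <- w$train$ratings$ratings
  expect_true(all(r >= cfg$likert_min & r <= cfg$likert_max))
})

test_that("two attributes with identical loadings are rank-identical when noiseless", {
  L <- rbind(a1 = c(1, 0.5), a2 = c(1, 0.5), a3 = c(0.2, 1))
  cfg <- synthetic_world_config(n_latent = 2, n_train_faces = 50, n_test_faces = 10,
                                n_attributes = 3, attribute_loadings = L,
                                rating_noise_sd = 0, seed = 5)
  w <- generate_world(cfg)
  r <- w$train$ratings$ratings
  expect_equal(spearman_rho(r[, "a1"], r[, "a2"]), 1)
})

test_that("designed latent-induced correlation is recovered empirically", {
  # cosine between loading rows = designed noiseless correlation
  L <- rbind(a1 = c(1, 0), a2 = c(0.6, 0.8), a3 = c(0, 1))
  cfg <- synthetic_world_config(n_latent = 2, n_train_faces = 2000, n_test_faces = 10,
                                n_attributes = 3, attribute_loadings = L,
                                rating_noise_sd = 0, seed = 8)
  w <- generate_world(cfg)
  r <- w$train$ratings$ratings
  expect_equal(cor(r[, "a1"], r[, "a2"]), 0.6, tolerance = 0.05)
  expect_equal(cor(r[, "a2"], r[, "a3"]), 0.8, tolerance = 0.05)
  expect_equal(abs(cor(r[, "a1"], r[, "a3"])), 0, tolerance = 0.05)
})

test_that("leading principal components carry the designed variance share", {
  # With unit-variance latent signal and noise sd chosen so that the top-2
  # eigenvalues of cov = LL' + s^2 I account for ~75% of total variance:
  # share = (sum top-2 eig(LL') + 2 s^2) / (n_attr (1 + s^2)).
  n_attr <- 14
  sigma <- sqrt(3.5 / 8.5)     # solves (14 + 2 s^2) / (14 (1 + s^2)) = 0.75
  shares <- vapply(1:20, function(s) {
    cfg <- synthetic_world_config(n_latent = 2, n_train_faces = 300,
                                  n_test_faces = 10, n_attributes = n_attr,
                                  rating_noise_sd = sigma, seed = 100 + s)
    w <- generate_world(cfg)
    ev <- eigen(cov(w$train$ratings$ratings), symmetric = TRUE,
                only.values = TRUE)$values
    sum(ev[1:2]) / sum(ev)
  }, numeric(1))
  expect_equal(mean(shares), 0.75, tolerance = 0.03)
})

test_that("rater averaging shrinks rating noise by sqrt(n_raters)", {
  base <- function(nr, seed) {
    cfg <- synthetic_world_config(n_latent = 2, n_train_faces = 3000,
                                  n_test_faces = 10, n_attributes = 2,
                                  attribute_loadings = rbind(a = c(1, 0), b = c(0, 1)),
                                  rating_noise_sd = 1, n_raters = nr,
                                  likert_min = -20, likert_max = 26, seed = seed)
    w <- generate_world(cfg)
    sig <- w$train$latent_scores[, 1] * (cfg$likert_max - cfg$likert_min) / 6
    resid <- w$train$ratings$ratings[, "a"] - sig
    # robust spread: the few faces clipped at the scale bounds carry large
    # residuals that are generator policy, not rater noise
    mad(resid)
  }
  expect_lt(abs(base(1, 21) - 1), 0.05)
  expect_lt(abs(base(16, 22) - 0.25), 0.02)
})

test_that("style perturbation honors sensitivity and leaves input untouched", {
  w <- make_small_world(9, specs = list(
    feature_space_spec("inv", 8, 0.7, 0.2, 0.1, style_sensitivity = 0),
    feature_space_spec("sens", 8, 0.7, 0.2, 0.1, style_sensitivity = 0.8)))
  inv <- w$test_sets[[1]]$features$inv
  sens <- w$test_sets[[1]]$features$sens
  out <- apply_style_perturbation(inv, w$config$feature_space_specs[[1]], seed = 1,
                                  style_perturbation_sd = 5)
  expect_identical(out$features, inv$features)
  # sensitivity 1 but zero scale: also untouched
  spec1 <- feature_space_spec("sens", 8, 0.7, 0.2, 0.1, style_sensitivity = 1)
  expect_identical(apply_style_perturbation(sens, spec1, seed = 1,
                                            style_perturbation_sd = 0)$features,
                   sens$features)
  pert <- apply_style_perturbation(sens, w$config$feature_space_specs[[2]], seed = 1,
                                   style_perturbation_sd = 5)
  expect_false(identical(pert$features, sens$features))
  expect_identical(pert$face_ids, sens$face_ids)
  # rank-one structure: displacement matrix has rank 1
  expect_equal(qr(pert$features - sens$features)$rank, 1)
  expect_error(apply_style_perturbation(sens, w$config$feature_space_specs[[1]], 1),
               "mismatch")
})

test_that("ambient test sets carry identity maps and per-identity images", {
  cfg <- synthetic_world_config(n_train_faces = 30, n_test_faces = 12,
                                n_attributes = 3, images_per_identity = 4, seed = 6)
  w <- generate_world(cfg)
  ts <- w$test_sets[[1]]
  expect_equal(length(ts$ratings$face_ids), 12 * 4)
  expect_equal(length(unique(ts$identity_map)), 12)
  expect_true(all(table(ts$identity_map) == 4))
  expect_identical(names(ts$identity_map), ts$ratings$face_ids)
})

test_that("invalid configurations are rejected with explanatory errors", {
  expect_error(synthetic_world_config(n_latent = 1), "n_latent")
  expect_error(synthetic_world_config(n_latent = 5, n_attributes = 4), "n_latent")
  expect_error(synthetic_world_config(
    n_latent = 2, n_attributes = 3,
    attribute_loadings = rbind(c(1, 1), c(2, 2), c(3, 3))), "rank")
  expect_error(feature_space_spec("x", 5, signal_fraction_shared = 0.7,
                                  signal_fraction_unique = 0.5), "<= 1")
  expect_error(synthetic_world_config(n_train_faces = -3), "n_train_faces")
})

test_that("world config round-trips through YAML", {
  cfg <- make_partition_config(4, n_train = 30L, n_test = 20L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_world_config(cfg, path)
  cfg2 <- read_world_config(path)
  expect_equal(cfg2$attribute_loadings, cfg$attribute_loadings,
               tolerance = 1e-12)
  expect_equal(cfg2$feature_space_specs, cfg$feature_space_specs,
               tolerance = 1e-12)
  expect_equal(generate_world(cfg)$train$ratings$ratings,
               generate_world(cfg2)$train$ratings$ratings, tolerance = 1e-9)
})

test_that("landmark sets are symmetric at zero asymmetry and scale cleanly", {
  lms <- generate_landmarks(4, asymmetry_sd = 0, seed = 2)
  pts <- lms[[1]]$points
  sym <- facejudge:::landmark_symmetry()
  mid_x <- mean(pts[sym$centers, 1])
  for (k in seq_len(nrow(sym$pairs))) {
    l <- pts[sym$pairs[k, 1], ]; r <- pts[sym$pairs[k, 2], ]
    expect_equal(l[1] - mid_x, -(r[1] - mid_x), tolerance = 1e-9)
    expect_equal(l[2], r[2], tolerance = 1e-9)
  }
  # doubling coordinates doubles all pairwise distances
  doubled <- landmark_set("d", pts * 2, lms[[1]]$skin_luminance)
  d1 <- dist(pts); d2 <- dist(doubled$points)
  expect_equal(as.vector(d2), 2 * as.vector(d1), tolerance = 1e-12)
  expect_error(generate_landmarks(3, asymmetry_sd = -1), "asymmetry_sd")
})

test_that("landmark sets round-trip through JSON", {
  lms <- generate_landmarks(3, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks_json(lms, path)
  back <- read_landmarks_json(path)
  expect_equal(back[[2]]$points, lms[[2]]$points, ignore_attr = TRUE)
  expect_equal(back[[2]]$skin_luminance, lms[[2]]$skin_luminance)
  expect_identical(back[[2]]$face_id, lms[[2]]$face_id)
})
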
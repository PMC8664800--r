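# Ridge / LASSO / OLS fitting with cross-validated regularization
# selection, prediction, and weight semantics.

make_xy <- function(n, p, seed, noise = 0, beta = NULL, collinear = FALSE) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    if (collinear) {
      z <- rnorm(n)
      X <- matrix(z, n, p) + 0.01 * X
    }
    beta <- beta %||% c(2, rep(0, p - 1))
    y <- drop(X %*% beta) + 1 + rnorm(n, sd = noise)
  })
  ft <- feature_table("toy", X, sprintf("f%03d", seq_len(n)))
  rt <- rating_table(cbind(attr = y), ft$face_ids, likert_min = min(y), likert_max = max(y))
  list(features = ft, ratings = rt, beta = beta)
}

test_that("OLS recovers exact linear structure noiselessly", {
  d <- make_xy(40, 4, seed = 1)
  m <- fit_attribute_model(d$features, d$ratings, "attr", fit_config(method = "ols"))
  raw_w <- m$weights / m$x_sd                 # back to raw-feature scale
  expect_equal(unname(raw_w), c(2, 0, 0, 0), tolerance = 1e-8)
  raw_int <- m$intercept - sum(raw_w * m$x_mean)
  expect_equal(raw_int, 1, tolerance = 1e-8)
  # fitted values match the closed-form OLS oracle
  preds <- predict(m, d$features)
  beta_hat <- qr.solve(cbind(1, d$features$features), d$ratings$ratings[, 1])
  oracle_fit <- unname(drop(cbind(1, d$features$features) %*% beta_hat))
  expect_equal(unname(preds), oracle_fit, tolerance = 1e-8)
})

test_that("ridge at fixed lambda equals the normal-equations oracle", {
  for (s in 1:5) {
    d <- make_xy(40, 6, seed = 100 + s, noise = 0.5,
                 beta = c(1.5, -1, 0.5, 0, 0, 0))
    lam <- c(0.7, 12, 400)[1 + (s %% 3)]
    m <- fit_attribute_model(d$features, d$ratings, "attr",
                             fit_config(method = "ridge", lambda_grid = lam))
    o <- oracle_ridge(d$features$features, d$ratings$ratings[, 1], lam)
    expect_equal(unname(m$weights), unname(o$weights), tolerance = 1e-8)
    expect_equal(m$intercept, o$intercept, tolerance = 1e-8)
  }
})

test_that("stronger ridge penalties shrink weights monotonically", {
  d <- make_xy(50, 5, seed = 3, noise = 0.3, beta = c(1, -1, 0.5, 0.2, 0))
  w_small <- fit_attribute_model(d$features, d$ratings, "attr",
                                 fit_config(lambda_grid = 1))$weights
  w_large <- fit_attribute_model(d$features, d$ratings, "attr",
                                 fit_config(lambda_grid = 1e5))$weights
  expect_lt(max(abs(w_large)), max(abs(w_small)))
  # near-zero penalty approaches OLS
  w_tiny <- fit_attribute_model(d$features, d$ratings, "attr",
                                fit_config(lambda_grid = 1e-8))$weights
  w_ols <- fit_attribute_model(d$features, d$ratings, "attr",
                               fit_config(method = "ols"))$weights
  expect_equal(unname(w_tiny), unname(w_ols), tolerance = 1e-5)
})

test_that("cross-validated selection is reproducible and shared across attributes", {
  w <- make_small_world(5, n_attributes = 3)
  ft <- w$train$features[[1]]
  rt <- w$train$ratings
  cfg <- fast_fit(seed = 9)
  m1 <- fit_attribute_model(ft, rt, "attr01", cfg)
  m2 <- fit_attribute_model(ft, rt, "attr01", cfg)
  expect_identical(m1$lambda_selected, m2$lambda_selected)
  expect_identical(m1$weights, m2$weights)
  # duplicated attribute column selects the same lambda and weights
  R2 <- cbind(rt$ratings, dup = rt$ratings[, "attr01"])
  rt2 <- rating_table(R2, rt$face_ids)
  ms <- fit_all_attributes(ft, rt2, cfg, attributes = c("attr01", "dup"))
  expect_identical(ms$attr01$lambda_selected, ms$dup$lambda_selected)
  expect_identical(unname(ms$attr01$weights), unname(ms$dup$weights))
})

test_that("prediction honors standardization, sign flips, and space guards", {
  w <- make_small_world(6)
  ft <- w$train$features[[1]]
  m <- fit_attribute_model(ft, w$train$ratings, "attr01", fast_fit())
  test_ft <- w$test_sets[[1]]$features[[1]]
  p <- predict(m, test_ft)
  pf <- predict(m, test_ft, flip_sign = TRUE)
  y <- w$test_sets[[1]]$ratings$ratings[, "attr01"]
  expect_equal(spearman_rho(pf, y), -spearman_rho(p, y), tolerance = 1e-12)
  # all-zero weights predict a constant equal to the intercept
  m0 <- m; m0$weights[] <- 0
  expect_equal(unname(predict(m0, test_ft)), rep(m$intercept, length(p)))
  other <- feature_table("other", test_ft$features, test_ft$face_ids)
  expect_error(predict(m, other), "mismatch")
})

test_that("LASSO fits run the same protocol and zero out noise features", {
  d <- make_xy(60, 6, seed = 11, noise = 0.2, beta = c(2, -1.5, 0, 0, 0, 0))
  cfg <- fit_config(method = "lasso", lambda_grid = 10^seq(-2, 1, length.out = 8),
                    n_cv_iterations = 30, seed = 4)
  m <- fit_attribute_model(d$features, d$ratings, "attr", cfg)
  expect_true(m$lambda_selected %in% cfg$lambda_grid)
  expect_gt(abs(m$weights[1]), abs(m$weights[4]))
  expect_gt(sum(abs(m$weights[3:6]) < 1e-6), 0)   # some true zeros dropped
  p <- predict(m, d$features)
  expect_gt(cor(p, d$ratings$ratings[, 1]), 0.95)
})

test_that("multicollinearity degrades OLS but not ridge out-of-sample", {
  wins <- 0L
  for (s in 1:5) {
    withr::with_seed(200 + s, {
      n <- 50; p <- 25
      z <- rnorm(n); X <- matrix(z, n, p) + 0.02 * matrix(rnorm(n * p), n, p)
      y <- z + rnorm(n, sd = 0.3)
      zt <- rnorm(30); Xt <- matrix(zt, 30, p) + 0.02 * matrix(rnorm(30 * p), 30, p)
      yt <- zt + rnorm(30, sd = 0.3)
    })
    ft <- feature_table("c", X, sprintf("a%02d", 1:n))
    rt <- rating_table(cbind(attr = y), ft$face_ids, likert_min = -10, likert_max = 10)
    ftt <- feature_table("c", Xt, sprintf("b%02d", 1:30))
    m_ridge <- fit_attribute_model(ft, rt, "attr", fast_fit(seed = s))
    m_ols <- fit_attribute_model(ft, rt, "attr", fit_config(method = "ols"))
    rho_ridge <- spearman_rho(predict(m_ridge, ftt), yt)
    rho_ols <- spearman_rho(predict(m_ols, ftt), yt)
    if (rho_ridge > rho_ols) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("degenerate inputs are rejected", {
  d <- make_xy(20, 3, seed = 21)
  const <- rating_table(cbind(attr = rep(4, 20)), d$features$face_ids)
  expect_error(fit_attribute_model(d$features, const, "attr", fit_config()),
               "constant")
  Xc <- d$features$features; Xc[, 2] <- 7
  ftc <- feature_table("toy", Xc, d$features$face_ids)
  expect_error(fit_attribute_model(ftc, d$ratings, "attr", fit_config()),
               "constant feature")
  expect_error(fit_attribute_model(d$features, d$ratings, "nope", fit_config()),
               "not present")
  small <- make_xy(8, 2, seed = 22)
  expect_error(fit_attribute_model(small$features, small$ratings, "attr",
                                   fit_config()), "at least 10")
})

test_that("fitted models round-trip through JSON", {
  w <- make_small_world(30)
  m <- fit_attribute_model(w$train$features[[1]], w$train$ratings, "attr01",
                           fast_fit())
  path <- withr::local_tempfile(fileext = ".json")
  write_fitted_model(m, path)
  back <- read_fitted_model(path)
  test_ft <- w$test_sets[[1]]$features[[1]]
  expect_equal(unname(predict(back, test_ft)), unname(predict(m, test_ft)),
               tolerance = 1e-12)
})
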
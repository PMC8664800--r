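# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive, separate computational route from the code under
# test.

# Average ranks computed from first principles: rank of x_i is
# (#smaller) + (#equal + 1) / 2.
oracle_ranks <- function(v) {
  vapply(v, function(x) sum(v < x) + (sum(v == x) + 1) / 2, numeric(1))
}

# Spearman correlation via explicit Pearson formula on oracle ranks.
oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x); ry <- oracle_ranks(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Ridge normal equations: (X'X + lambda I)^-1 X'y on a standardized,
# centered problem; intercept = mean(y).
oracle_ridge <- function(X, y, lambda) {
  mu <- colMeans(X); sdv <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  yc <- y - mean(y)
  w <- solve(crossprod(Xs) + diag(lambda, ncol(Xs)), crossprod(Xs, yc))
  list(weights = drop(w), intercept = mean(y))
}

# Benjamini-Hochberg step-up, written directly from the definition:
# q_(i) = min_{j >= i} m * p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  p_sorted <- p[ord]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(m * p_sorted[i:m] / seq(i, m))
  }, numeric(1))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# All permutations of 1..n by iterative insertion (independent of the
# package's recursive construction).
oracle_permutations <- function(n) {
  perms <- list(1L)
  for (k in 2:n) {
    perms <- unlist(lapply(perms, function(p) {
      lapply(seq_len(k), function(pos) append(p, k, after = pos - 1L))
    }), recursive = FALSE)
  }
  do.call(rbind, perms)
}

# Small synthetic world with a designed rating-variance partition between
# two spaces: latent 1 visible to both, latent 2 only to A, latent 3 only
# to B; attr01 carries variance fractions 0.4 (shared), 0.2 (A-unique),
# 0.1 (B-unique) and 0.3 rater noise.
make_partition_config <- function(seed, n_train = 1500L, n_test = 1000L) {
  L <- rbind(attr01 = sqrt(c(0.4, 0.2, 0.1)),
             attr02 = sqrt(c(0.5, 0.1, 0.1)),
             attr03 = sqrt(c(0.2, 0.4, 0.1)))
  synthetic_world_config(
    n_latent = 3L, n_train_faces = n_train, n_test_faces = n_test,
    n_attributes = 3L, attribute_loadings = L,
    rating_noise_sd = sqrt(3 / 7), n_raters = 1L,
    feature_space_specs = list(
      feature_space_spec("A", 15L, signal_fraction_shared = 0.85,
                         signal_fraction_unique = 0.05, noise_sd = 0.05,
                         latent_subset = c(1L, 2L)),
      feature_space_spec("B", 15L, signal_fraction_shared = 0.85,
                         signal_fraction_unique = 0.05, noise_sd = 0.05,
                         latent_subset = c(1L, 3L))),
    seed = seed)
}

# A small, quiet world for fast fitting tests.
make_small_world <- function(seed, n_train = 100L, n_test = 60L,
                             n_attributes = 3L, rating_noise_sd = 0.3,
                             specs = NULL) {
  specs <- specs %||% list(
    feature_space_spec("spaceA", 10L, signal_fraction_shared = 0.8,
                       signal_fraction_unique = 0.1, noise_sd = 0.05))
  generate_world(synthetic_world_config(
    n_latent = 2L, n_train_faces = n_train, n_test_faces = n_test,
    n_attributes = n_attributes, rating_noise_sd = rating_noise_sd,
    feature_space_specs = specs, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fast_fit <- function(seed = 1L, n_lambda = 8L, n_cv = 40L) {
  fit_config(lambda_grid = 10^seq(0, 5, length.out = n_lambda),
             n_cv_iterations = n_cv, seed = seed)
}
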
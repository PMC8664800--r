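# Internal helpers shared across modules.

#' Derive a stage-specific seed from a global seed
#'
#' All randomness in the package flows through explicit seeds. Pipeline
#' stages and per-cell analyses derive their own seed deterministically from
#' a global seed plus a stage label, so that no two stages share a random
#' stream and a whole run is reproducible from a single integer.
#'
#' @param seed Integer global seed.
#' @param stage Character label naming the consumer of the derived seed.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "fit")
#' derive_seed(1L, "evaluate")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.character(stage), length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h * 1299721) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with a caller-facing message (no call in output).
fj_stop <- function(...) stop(..., call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    fj_stop(sprintf("'%s' must be a single integer >= %d (got %s)",
                    name, min, paste(format(x), collapse = ", ")))
  }
  as.integer(x)
}

assert_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    fj_stop(sprintf("'%s' must be a single number in [0, 1]", name))
  }
  as.numeric(x)
}

# Random 80/20-style split index sets, shared across attributes so that
# regularization selection is comparable between models fitted to the same
# faces. Splits are sampled independently per iteration (not k-fold).
make_cv_splits <- function(n, n_iterations, validation_fraction, seed) {
  n_val <- max(1L, round(n * validation_fraction))
  if (n_val >= n) fj_stop("validation fraction leaves no training samples")
  withr::with_seed(seed, {
    lapply(seq_len(n_iterations), function(i) {
      val <- sample.int(n, n_val)
      list(train = setdiff(seq_len(n), val), val = val)
    })
  })
}
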
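#' Sequential floating-point sum in an explicit order
#'
#' Left-to-right sequential summation of `values[order]` in IEEE-754 double
#' precision with no compensation and no reassociation. Because
#' floating-point addition is not associative, different orders can give
#' different results — the exact mechanism by which atomic-add based sum
#' reductions on GPUs produce nondeterministic results when the scheduling
#' order of parallel threads varies. The same order always gives the
#' bit-identical result.
#'
#' @param values Numeric vector.
#' @param order A permutation of `seq_along(values)` (1-based).
#' @return The ordered sum; `0.0` for empty input (empty-sum convention).
#' @examples
#' ordered_sum(c(1e16, 1, -1e16), c(1, 2, 3))  # 0: the 1 is absorbed
#' ordered_sum(c(1e16, 1, -1e16), c(1, 3, 2))  # 1
#' @export
ordered_sum <- function(values, order = seq_along(values)) {
  stopifnot(is.numeric(values))
  n <- length(values)
  if (length(order) != n || (n > 0L && !identical(sort(as.integer(order)),
                                                 seq_len(n)))) {
    detml_stop("'order' must be a permutation of seq_along(values)",
               class = "detml_validation_error")
  }
  acc <- 0
  for (i in seq_len(n)) acc <- acc + values[[order[[i]]]]
  acc
}

#' Synthetic linear-regression task
#'
#' Desk-scale stand-in for a training workload: a reproducible design
#' matrix, generating weights and Gaussian-noise targets. Linear regression
#' is used (rather than a neural network) because a closed-form solution is
#' available as an independent check and the determinism machinery, not
#' model capacity, is what the toolkit exercises. The same seed yields a
#' bit-identical task.
#'
#' @param n_samples Number of rows (default 200).
#' @param n_features Number of columns (default 5); must be `<= n_samples`.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (default 0.1; `0` gives exactly linear targets).
#' @param seed Generation seed (default 0).
#' @return A `detml_toy_task` list: `X`, `y`, `weights`, `noise_sd`, `seed`.
#' @export
make_toy_task <- function(n_samples = 200L, n_features = 5L, noise_sd = 0.1,
                          seed = 0L) {
  if (!(n_samples >= n_features && n_features >= 1L)) {
    detml_stop("need n_samples >= n_features >= 1 (got %d, %d)",
               n_samples, n_features, class = "detml_validation_error")
  }
  if (noise_sd < 0) {
    detml_stop("noise_sd must be >= 0", class = "detml_validation_error")
  }
  with_seed(seed, {
    X <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
    w <- stats::rnorm(n_features)
    y <- as.numeric(X %*% w) +
      if (noise_sd > 0) stats::rnorm(n_samples, sd = noise_sd) else 0
    structure(list(X = X, y = y, weights = w, noise_sd = noise_sd,
                   seed = as.integer(seed)),
              class = "detml_toy_task")
  })
}

#' Export / import a toy task as CSV
#'
#' Writes the design matrix and targets as a plain CSV (columns `x1..xp`,
#' `y`) for cross-implementation checks.
#'
#' @param task A `detml_toy_task`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_toy_task <- function(task, path) {
  df <- as.data.frame(task$X)
  names(df) <- paste0("x", seq_len(ncol(task$X)))
  df$y <- task$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# digest of a task's defining bytes (used by reproducibility tests)
task_digest <- function(task) {
  raw_digest(serialize_params(c(as.numeric(task$X), task$y, task$weights)))
}

#' Train the toy task under a run setting
#'
#' Full-batch gradient descent on mean-squared error where every reduction
#' (the per-feature gradient sums and the loss itself) goes through
#' [ordered_sum()] under a reduction policy chosen from the setting:
#'
#' * `deterministic` mode: fixed sequential order, seeded initialization —
#'   bit-reproducible by construction.
#' * `seeds` mode, `device_profile = "cpu"`: fixed order, seeded
#'   initialization — bit-reproducible (seeding suffices when the
#'   accumulation order is fixed).
#' * `seeds` or `random` mode, `device_profile = "gpu-sim"`: the summation
#'   order is reshuffled every epoch from OS entropy, simulating
#'   nondeterministic atomic-add scheduling; seeding cannot tame it.
#' * `random` mode additionally draws the weight initialization from OS
#'   entropy.
#'
#' Conforms to the harness training contract:
#' `trainer(plan, setting, epochs)` returning
#' `list(trajectory, params)`.
#'
#' @param task A [make_toy_task()] result.
#' @param setting A [run_setting()].
#' @param epochs Number of gradient steps (>= 1).
#' @param lr Learning rate (default 0.05).
#' @return `list(trajectory = per-epoch MSE, params = final weights)`.
#' @export
toy_train <- function(task, setting, epochs, lr = 0.05) {
  stopifnot(inherits(task, "detml_toy_task"), inherits(setting, "detml_run_setting"))
  if (epochs < 1L) {
    detml_stop("epochs must be >= 1", class = "detml_validation_error")
  }
  n <- nrow(task$X); p <- ncol(task$X)
  shuffle <- setting$mode %in% c("random", "seeds") &&
    identical(setting$device_profile, "gpu-sim")
  w <- if (setting$mode == "random") {
    urandom_normal(p) * 0.1
  } else {
    with_seed(setting$seed, stats::rnorm(p) * 0.1)
  }
  traj <- numeric(epochs)
  for (e in seq_len(epochs)) {
    # residuals accumulated elementwise (no BLAS reassociation)
    r <- -task$y
    for (j in seq_len(p)) r <- r + task$X[, j] * w[j]
    # each reduction gets its own order, as every GPU kernel launch
    # schedules its atomic adds independently
    g <- numeric(p)
    for (j in seq_len(p)) {
      ord <- if (shuffle) urandom_permutation(n) else seq_len(n)
      g[j] <- 2 * ordered_sum(task$X[, j] * r, ord) / n
    }
    ord <- if (shuffle) urandom_permutation(n) else seq_len(n)
    traj[e] <- ordered_sum(r * r, ord) / n
    w <- w - lr * g
  }
  list(trajectory = traj, params = w)
}

#' Built-in toy trainer conforming to the harness training contract
#'
#' @param task A [make_toy_task()] result (defaults to the standard
#'   200 x 5 task).
#' @param lr Learning rate passed through to [toy_train()].
#' @return A function `(plan, setting, epochs)` suitable for
#'   [execute_runs()].
#' @export
make_toy_trainer <- function(task = make_toy_task(), lr = 0.05) {
  force(task); force(lr)
  function(plan, setting, epochs) {
    toy_train(task, setting, epochs, lr = lr)
  }
}
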
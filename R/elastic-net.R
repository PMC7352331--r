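#' Elastic-net configuration
#'
#' Hyperparameter grids and solver settings for the penalized regression
#' stage. Defaults follow the common screen-modeling protocol: alpha over
#' `{0.1, ..., 1.0}`, an automatic 100-point lambda path from
#' `lambda_max` down by a factor of 1e-3, penalty selection by 10-fold
#' cross-validation averaged over 100 random fold re-partitions.
#'
#' @param alpha_grid L1 mixing values in (0, 1].
#' @param lambda_grid Optional explicit descending positive lambda path;
#'   `NULL` (default) auto-generates a path per `alpha` from the data.
#' @param n_lambda,lambda_min_ratio Auto-path length and terminal ratio.
#' @param n_folds Cross-validation folds (>= 2).
#' @param n_cv_iterations Random fold re-partitions to average over.
#' @param cv_rule `"min"` picks the lowest mean CV error (ties toward
#'   larger lambda, then smaller alpha); `"1se"` picks the sparsest pair
#'   within one standard error of the minimum.
#' @param tol Convergence threshold on the per-sweep objective decrease.
#' @param max_iter Sweep cap per lambda.
#' @param seed Integer seed for fold assignment (and downstream
#'   bootstraps).
#' @return A list of class `enet_config`.
#' @export
enet_config <- function(alpha_grid = seq(0.1, 1, by = 0.1),
                        lambda_grid = NULL,
                        n_lambda = 100, lambda_min_ratio = 1e-3,
                        n_folds = 10, n_cv_iterations = 100,
                        cv_rule = c("min", "1se"),
                        tol = 1e-8, max_iter = 100000L, seed = 1L) {
  if (!length(alpha_grid) || any(alpha_grid <= 0 | alpha_grid > 1)) {
    abort("`alpha_grid` must be non-empty with values in (0, 1].")
  }
  if (!is.null(lambda_grid)) {
    if (!length(lambda_grid) || any(lambda_grid <= 0) ||
        is.unsorted(rev(lambda_grid), strictly = FALSE)) {
      abort("`lambda_grid` must be positive and descending.")
    }
  }
  stop_not_count(n_lambda, "n_lambda")
  stop_not_scalar(lambda_min_ratio, "lambda_min_ratio", lo = 0, hi = 1,
                  lo_open = TRUE, hi_open = TRUE)
  stop_not_count(n_folds, "n_folds")
  if (n_folds < 2) abort("`n_folds` must be at least 2.")
  stop_not_count(n_cv_iterations, "n_cv_iterations")
  stop_not_scalar(tol, "tol", lo = 0, lo_open = TRUE)
  stop_not_count(max_iter, "max_iter")
  structure(list(
    alpha_grid = as.numeric(alpha_grid), lambda_grid = lambda_grid,
    n_lambda = as.integer(n_lambda), lambda_min_ratio = lambda_min_ratio,
    n_folds = as.integer(n_folds),
    n_cv_iterations = as.integer(n_cv_iterations),
    cv_rule = match.arg(cv_rule),
    tol = tol, max_iter = as.integer(max_iter), seed = as.integer(seed)
  ), class = "enet_config")
}

check_xy_ <- function(X, y) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    abort("X and y must be finite with no missing values.")
  }
  if (nrow(X) != length(y)) abort("nrow(X) must equal length(y).")
  X
}

#' Smallest lambda that zeroes all coefficients, and the automatic path
#'
#' `lambda_max = max_j |x_j' (y - mean(y))| / (n * alpha)`; the automatic
#' path descends geometrically from `lambda_max` to
#' `lambda_max * lambda_min_ratio`.
#'
#' @param X Feature matrix (observations x features).
#' @param y Response vector.
#' @param alpha L1 mixing parameter in (0, 1].
#' @param n_lambda,lambda_min_ratio Path length and terminal ratio.
#' @return `lambda_max()`: a scalar. `lambda_path()`: a descending vector.
#' @export
lambda_max <- function(X, y, alpha) {
  X <- check_xy_(X, y)
  stop_not_scalar(alpha, "alpha", lo = 0, hi = 1, lo_open = TRUE)
  max(abs(crossprod(X, y - mean(y)))) / (nrow(X) * alpha)
}

#' @rdname lambda_max
#' @export
lambda_path <- function(X, y, alpha, n_lambda = 100,
                        lambda_min_ratio = 1e-3) {
  lmax <- lambda_max(X, y, alpha)
  if (lmax <= 0) lmax <- 1e-3  # response is constant; any path works
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' Fit the elastic net by cyclic coordinate descent
#'
#' Minimizes
#' `(1/2n) * sum((y - b0 - X %*% beta)^2) + lambda * (alpha * ||beta||_1 +
#' (1 - alpha)/2 * ||beta||_2^2)`
#' with soft-thresholding coordinate updates and an unpenalized intercept.
#' The solver is deterministic given its inputs; each coordinate update is
#' an exact one-dimensional minimizer, so the objective never increases.
#' Columns of `X` are used as given — standardize features upstream (see
#' [zscore_expression()]) so weights are comparable across genes.
#'
#' @inheritParams lambda_max
#' @param lambda Non-negative penalty strength (scalar).
#' @param tol,max_iter Convergence control, see [enet_config()].
#' @param beta_init Optional warm-start coefficient vector.
#' @param record_objective Keep the per-sweep objective trace (for
#'   diagnostics).
#' @return An object of class `enet_fit`: `beta` (named), `intercept`,
#'   `alpha`, `lambda`, `n_iter`, `converged`, and optionally
#'   `objective`.
#' @export
#' @examples
#' X <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("g", 1:5)))
#' y <- X[, 1] + rnorm(20, sd = 0.1)
#' fit <- enet_fit(X, y, alpha = 0.5, lambda = 0.05)
#' tidy(fit)
enet_fit <- function(X, y, alpha, lambda, tol = 1e-8, max_iter = 100000L,
                     beta_init = NULL, record_objective = FALSE) {
  X <- check_xy_(X, y)
  stop_not_scalar(alpha, "alpha", lo = 0, hi = 1, lo_open = TRUE)
  stop_not_scalar(lambda, "lambda", lo = 0)
  res <- .cd_enet_path(X, as.numeric(y), alpha, lambda, tol,
                       as.integer(max_iter), beta_init, record_objective)
  beta <- drop(res$beta)
  names(beta) <- colnames(X)
  structure(list(
    beta = beta, intercept = res$intercept[1], alpha = alpha,
    lambda = lambda, n_iter = res$n_iter[1],
    converged = res$converged[1],
    objective = if (record_objective) res$objective[[1]] else NULL
  ), class = "enet_fit")
}

#' Fit an elastic-net path with warm starts
#'
#' @inheritParams enet_fit
#' @param lambda Descending positive lambda vector.
#' @return List with `beta` (features x lambda matrix), `intercept`,
#'   `lambda`, `n_iter`, `converged`.
#' @export
enet_path_fit <- function(X, y, alpha, lambda, tol = 1e-8,
                          max_iter = 100000L, beta_init = NULL) {
  X <- check_xy_(X, y)
  stop_not_scalar(alpha, "alpha", lo = 0, hi = 1, lo_open = TRUE)
  res <- .cd_enet_path(X, as.numeric(y), alpha, as.numeric(lambda), tol,
                       as.integer(max_iter), beta_init, FALSE)
  rownames(res$beta) <- colnames(X)
  list(beta = res$beta, intercept = res$intercept,
       lambda = as.numeric(lambda), n_iter = res$n_iter,
       converged = res$converged)
}

#' Elastic-net objective value
#'
#' @inheritParams enet_fit
#' @param beta Coefficient vector.
#' @param intercept Intercept scalar.
#' @return The penalized objective (scalar).
#' @export
enet_objective <- function(X, y, beta, intercept, alpha, lambda) {
  X <- check_xy_(X, y)
  r <- y - intercept - drop(X %*% beta)
  sum(r^2) / (2 * nrow(X)) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

#' @export
print.enet_fit <- function(x, ...) {
  cat(sprintf("<enet_fit> alpha=%.3g lambda=%.4g | %d/%d nonzero | %s in %d sweeps\n",
              x$alpha, x$lambda, sum(x$beta != 0), length(x$beta),
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$n_iter))
  invisible(x)
}

#' @method tidy enet_fit
#' @export
tidy.enet_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$beta) %||% paste0("x", seq_along(x$beta))),
         estimate = c(x$intercept, unname(x$beta)))
}

#' @method glance enet_fit
#' @export
glance.enet_fit <- function(x, ...) {
  tibble(alpha = x$alpha, lambda = x$lambda,
         n_nonzero = sum(x$beta != 0), n_iter = x$n_iter,
         converged = isTRUE(x$converged))
}

#' Choose alpha and lambda by repeated k-fold cross-validation
#'
#' For each of `n_cv_iterations` random partitions into `n_folds` folds,
#' fits the lambda path on each training split and records held-out mean
#' squared error; errors are averaged over folds and iterations, and the
#' (alpha, lambda) pair minimizing the mean CV error is returned, with
#' ties broken toward larger lambda (sparser), then smaller alpha. The
#' `"1se"` rule instead returns the largest lambda (then smallest alpha)
#' whose mean error is within one standard error of the minimum.
#'
#' @inheritParams lambda_max
#' @param cfg An [enet_config()].
#' @return List of class `enet_cv`: `alpha`, `lambda`, `cv_curve` (tibble
#'   of `alpha`, `lambda`, `mse`, `se`), and the winning row.
#' @export
enet_cv <- function(X, y, cfg = enet_config()) {
  X <- check_xy_(X, y)
  n <- nrow(X)
  if (n < cfg$n_folds) abort("Need at least `n_folds` observations.")

  paths <- lapply(cfg$alpha_grid, function(a) {
    if (is.null(cfg$lambda_grid)) {
      lambda_path(X, y, a, cfg$n_lambda, cfg$lambda_min_ratio)
    } else {
      as.numeric(cfg$lambda_grid)
    }
  })

  # accumulate held-out squared errors per (alpha, lambda)
  sums <- lapply(paths, function(p) numeric(length(p)))
  sq_sums <- lapply(paths, function(p) numeric(length(p)))
  n_cells <- cfg$n_cv_iterations * cfg$n_folds

  with_seed_(cfg$seed, {
    for (it in seq_len(cfg$n_cv_iterations)) {
      fold <- sample(rep(seq_len(cfg$n_folds), length.out = n))
      for (ai in seq_along(cfg$alpha_grid)) {
        a <- cfg$alpha_grid[ai]
        lam <- paths[[ai]]
        for (k in seq_len(cfg$n_folds)) {
          test <- fold == k
          fit <- enet_path_fit(X[!test, , drop = FALSE], y[!test], a, lam,
                               tol = cfg$tol, max_iter = cfg$max_iter)
          pred <- X[test, , drop = FALSE] %*% fit$beta +
            rep(fit$intercept, each = sum(test))
          mse_k <- colMeans((pred - y[test])^2)
          sums[[ai]] <- sums[[ai]] + mse_k
          sq_sums[[ai]] <- sq_sums[[ai]] + mse_k^2
        }
      }
    }
  })

  curve <- purrr::map2_dfr(seq_along(cfg$alpha_grid), paths, function(ai, lam) {
    m <- sums[[ai]] / n_cells
    v <- pmax(sq_sums[[ai]] / n_cells - m^2, 0)
    tibble(alpha = cfg$alpha_grid[ai], lambda = lam, mse = m,
           se = sqrt(v / n_cells))
  })

  ord <- order(curve$mse, -curve$lambda, curve$alpha)
  best <- curve[ord[1], ]
  if (cfg$cv_rule == "1se") {
    ok <- curve$mse <= best$mse + best$se
    cand <- curve[ok, ]
    cand <- cand[order(-cand$lambda, cand$alpha), ]
    best <- cand[1, ]
  }
  structure(list(alpha = best$alpha, lambda = best$lambda,
                 cv_curve = curve, best = best, rule = cfg$cv_rule),
            class = "enet_cv")
}

#' @export
print.enet_cv <- function(x, ...) {
  cat(sprintf("<enet_cv> rule=%s alpha*=%.3g lambda*=%.4g (mean CV MSE %.4g)\n",
              x$rule, x$alpha, x$lambda, x$best$mse))
  invisible(x)
}
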
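# Independent oracles and small fixtures used across the suite.

# glmnet as an independent elastic-net oracle. glmnet internally
# standardizes the gaussian response by its 1/n-denominator SD, so for
# alpha < 1 its (alpha, lambda) parameterize a slightly different objective
# than the textbook one this package minimizes. Remapping
#   k = alpha + s*(1-alpha),  alpha_g = alpha/k,  lambda_g = lambda*k
# (s = sd_n(y)) makes the two objectives identical; with this remap the
# objective gap between the two solvers is at machine precision.
glmnet_oracle_coef <- function(X, y, alpha, lambda) {
  s <- sqrt(mean((y - mean(y))^2))
  k <- alpha + s * (1 - alpha)
  a_g <- alpha / k
  lam_g <- lambda * k
  path <- exp(seq(log(max(lam_g * 50, 1)), log(lam_g), length.out = 40))
  g <- glmnet::glmnet(X, y, alpha = a_g, lambda = path,
                      standardize = FALSE, thresh = 1e-14)
  as.numeric(stats::coef(g)[, ncol(stats::coef(g))])  # (intercept, beta)
}

# random regression problem with named feature columns
rand_problem <- function(n, p, seed, signal = NULL, noise_sd = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("g%03d", 1:p)))
  y <- rnorm(n, sd = noise_sd)
  if (!is.null(signal)) y <- y + drop(X[, seq_along(signal), drop = FALSE] %*% signal)
  list(X = X, y = y)
}

# column-centered matrix with orthonormal-up-to-sqrt(n) columns
# (x_j'x_j = n, x_j'x_k = 0, colMeans = 0), for closed-form checks
orthonormal_design <- function(n, p, seed) {
  set.seed(seed)
  M <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  qr.Q(qr(M)) * sqrt(n)
}

# fast elastic-net settings for simulation-heavy tests; grids are the
# package's scaled-down analysis settings, not tuned per test
quick_enet_cfg <- function(seed = 1L) {
  enet_config(alpha_grid = c(0.2, 0.5, 1), n_lambda = 50,
              n_cv_iterations = 3, n_folds = 10, seed = seed)
}

# small two-drug screen with one shared sensitivity marker
shared_marker_effects <- function(effect_b = -1) {
  dplyr::bind_rows(planted_effect("g0001", "d001", effect_b),
                   planted_effect("g0001", "d002", effect_b))
}

# brute-force quantile-normalization oracle for tie-free matrices:
# map each column's ranks onto the row means of the sorted columns
qn_oracle_no_ties <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) ref[rank(col)])
}
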
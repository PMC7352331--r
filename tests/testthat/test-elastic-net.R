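test_that("lambda at or above lambda_max shrinks every coefficient to zero", {
  pr <- rand_problem(25, 8, seed = 1, signal = c(1, -0.5))
  for (a in c(0.3, 1)) {
    lmax <- lambda_max(pr$X, pr$y, a)
    f <- enet_fit(pr$X, pr$y, a, lmax * 1.000001)
    expect_true(all(f$beta == 0))
    expect_equal(f$intercept, mean(pr$y))
    f2 <- enet_fit(pr$X, pr$y, a, lmax * 0.9)
    expect_gt(sum(f2$beta != 0), 0)
  }
})

test_that("the unpenalized limit reproduces least squares", {
  pr <- rand_problem(40, 5, seed = 2, signal = c(2, 0, -1))
  f <- enet_fit(pr$X, pr$y, alpha = 1, lambda = 0, tol = 1e-14)
  ols <- unname(coef(lm(pr$y ~ pr$X)))
  expect_lt(max(abs(c(f$intercept, unname(f$beta)) - ols)), 1e-6)
})

test_that("orthonormal designs recover the soft-threshold closed form", {
  n <- 36
  X <- orthonormal_design(n, 4, seed = 3)
  set.seed(33)
  y <- drop(X %*% c(0.4, -0.2, 0.05, 0)) + rnorm(n, sd = 0.3)
  z <- drop(crossprod(X, y - mean(y))) / n
  for (lam in c(0.02, 0.1, 0.3)) {
    f <- enet_fit(X, y, alpha = 1, lambda = lam, tol = 1e-14)
    expect_equal(unname(f$beta), sign(z) * pmax(abs(z) - lam, 0),
                 tolerance = 1e-8)
  }
  # general elastic net on the same design: S(z, lam*a) / (1 + lam*(1-a))
  a <- 0.4; lam <- 0.1
  f <- enet_fit(X, y, alpha = a, lambda = lam, tol = 1e-14)
  expect_equal(unname(f$beta),
               sign(z) * pmax(abs(z) - lam * a, 0) / (1 + lam * (1 - a)),
               tolerance = 1e-8)
})

test_that("the objective never increases across coordinate-descent sweeps", {
  for (s in 1:5) {
    pr <- rand_problem(20, 10, seed = s, signal = c(1.5, -1))
    f <- enet_fit(pr$X, pr$y, alpha = 0.5, lambda = 0.05,
                  record_objective = TRUE)
    expect_true(all(diff(f$objective) <= 1e-12))
    expect_true(f$converged)
  }
})

test_that("solutions agree with the remapped glmnet oracle", {
  set.seed(7)
  for (i in 1:20) {
    pr <- rand_problem(10, 5, seed = 100 + i, signal = 1)
    a <- sample(c(0.2, 0.5, 0.8, 1), 1)
    lam <- runif(1, 0.02, 0.3)
    f <- enet_fit(pr$X, pr$y, a, lam, tol = 1e-14)
    cg <- glmnet_oracle_coef(pr$X, pr$y, a, lam)
    o_mine <- enet_objective(pr$X, pr$y, f$beta, f$intercept, a, lam)
    o_orc <- enet_objective(pr$X, pr$y, cg[-1], cg[1], a, lam)
    expect_lt(abs(o_mine - o_orc), 1e-5)
  }
})

test_that("a generic convex minimizer cannot beat the solver's objective", {
  pr <- rand_problem(15, 4, seed = 9, signal = c(1, -1))
  a <- 0.6; lam <- 0.08
  f <- enet_fit(pr$X, pr$y, a, lam, tol = 1e-14)
  obj <- function(par) enet_objective(pr$X, pr$y, par[-1], par[1], a, lam)
  nm <- optim(rep(0, 5), obj, method = "Nelder-Mead",
              control = list(maxit = 20000, reltol = 1e-14))
  expect_lte(obj(c(f$intercept, f$beta)), nm$value + 1e-6)
})

test_that("warm starts along the path match cold starts", {
  pr <- rand_problem(30, 12, seed = 4, signal = c(1, -1, 0.5))
  lam <- lambda_path(pr$X, pr$y, 0.5, n_lambda = 20)
  warm <- enet_path_fit(pr$X, pr$y, 0.5, lam, tol = 1e-12)
  for (k in c(1, 7, 14, 20)) {
    cold <- enet_fit(pr$X, pr$y, 0.5, lam[k], tol = 1e-12)
    expect_equal(unname(warm$beta[, k]), unname(cold$beta), tolerance = 1e-6)
  }
})

test_that("support size is (near-)monotone along a descending lambda path", {
  viol <- 0
  for (s in 1:5) {
    pr <- rand_problem(30, 15, seed = 20 + s, signal = c(1, -1))
    lam <- lambda_path(pr$X, pr$y, 1, n_lambda = 40)
    fit <- enet_path_fit(pr$X, pr$y, 1, lam, tol = 1e-12)
    supp <- colSums(abs(fit$beta) > 1e-10)
    viol <- viol + sum(diff(supp) < 0)
  }
  # descending lambda should grow the support; rare single-feature swaps
  # near ties are tolerated and counted, not failed individually
  expect_lte(viol, 5)
})

test_that("cross-validation degenerates correctly and breaks ties sparsely", {
  pr <- rand_problem(30, 5, seed = 5, signal = 1)
  cfg1 <- enet_config(alpha_grid = 0.5, lambda_grid = 0.07, n_folds = 5,
                      n_cv_iterations = 2, seed = 1)
  cv1 <- enet_cv(pr$X, pr$y, cfg1)
  expect_equal(cv1$alpha, 0.5)
  expect_equal(cv1$lambda, 0.07)

  # two lambdas both above lambda_max give identical (null) fits ->
  # exact MSE tie -> the larger lambda wins; same for duplicated alphas
  lmax <- max(vapply(c(0.4, 0.8), function(a) lambda_max(pr$X, pr$y, a),
                     numeric(1)))
  cfg2 <- enet_config(alpha_grid = c(0.8, 0.4),
                      lambda_grid = c(lmax * 3, lmax * 2),
                      n_folds = 5, n_cv_iterations = 2, seed = 1)
  cv2 <- enet_cv(pr$X, pr$y, cfg2)
  expect_equal(cv2$lambda, lmax * 3)
  expect_equal(cv2$alpha, 0.4)
})

test_that("pure-noise responses select heavy shrinkage", {
  hits <- 0
  for (s in 1:20) {
    pr <- rand_problem(100, 20, seed = 200 + s)  # y independent of X
    cfg <- enet_config(alpha_grid = 0.5, n_lambda = 100,
                       n_cv_iterations = 10, n_folds = 10, seed = s)
    cv <- enet_cv(pr$X, pr$y, cfg)
    lam <- sort(unique(cv$cv_curve$lambda), decreasing = TRUE)
    hits <- hits + (cv$lambda >= lam[ceiling(length(lam) / 10)])
  }
  expect_gte(hits, 16)  # >= 80% of runs in the top decile of the path
})

test_that("a dominant predictor survives cross-validated selection", {
  hits <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    X <- matrix(rnorm(50 * 20), 50, 20,
                dimnames = list(NULL, sprintf("g%03d", 1:20)))
    y <- 2 * X[, 1] + rnorm(50, sd = sqrt(4 / 10))  # SNR 10
    cfg <- enet_config(alpha_grid = c(0.5, 1), n_lambda = 50,
                       n_cv_iterations = 2, n_folds = 10, seed = s)
    cv <- enet_cv(X, y, cfg)
    refit <- enet_fit(X, y, cv$alpha, cv$lambda)
    hits <- hits + (abs(refit$beta["g001"]) > 1e-10)
  }
  expect_gte(hits, 19)  # >= 95% of 20 seeded runs
})

test_that("non-finite inputs are rejected and tidiers summarize fits", {
  pr <- rand_problem(10, 3, seed = 6)
  Xb <- pr$X; Xb[1, 1] <- NA
  expect_error(enet_fit(Xb, pr$y, 1, 0.1), "finite")
  f <- enet_fit(pr$X, pr$y, 0.5, 0.05)
  td <- tidy(f)
  expect_equal(td$term[1], "(Intercept)")
  expect_equal(nrow(td), 4)
  gl <- glance(f)
  expect_true(gl$converged)
  expect_equal(gl$alpha, 0.5)
})
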
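# GPR/GPC core: kernel, evidence, fitting, dual/primal equivalence, Laplace GPC.

test_that("linear kernel matches the naive double loop and is PSD", {
  expect_equal(linear_kernel(diag(2)), diag(2))
  set.seed(41)
  Xa <- matrix(rnorm(12), 4, 3); Xb <- matrix(rnorm(6), 2, 3)
  K <- linear_kernel(Xa, Xb)
  for (i in 1:4) for (j in 1:2)
    expect_equal(K[i, j], sum(Xa[i, ] * Xb[j, ]), tolerance = 1e-12)
  expect_gte(min(eigen(linear_kernel(Xa), symmetric = TRUE)$values), -1e-10)
  expect_error(linear_kernel(Xa, matrix(0, 2, 2)), "mismatch")
})

test_that("log marginal likelihood matches hand and dense oracles", {
  # n=1, K=1, theta=sigma2=1, y=mu=0: log N(0 | 0, 2)
  expect_equal(log_marginal_likelihood(matrix(1), 0, 1, 1, 0),
               -0.5 * log(2) - 0.5 * log(2 * pi), tolerance = 1e-12)
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    K <- linear_kernel(X)
    y <- rnorm(n)
    th <- runif(1, 0.1, 2); s2 <- runif(1, 0.1, 2); mu <- rnorm(1)
    expect_equal(log_marginal_likelihood(K, y, th, s2, mu),
                 oracle_lml(K, y, th, s2, mu), tolerance = 1e-8)
    # translation invariance: shift y and mu together
    expect_equal(log_marginal_likelihood(K, y + 3, th, s2, mu + 3),
                 log_marginal_likelihood(K, y, th, s2, mu), tolerance = 1e-10)
  }
})

test_that("two-point toy model: alpha, prediction and weights by hand", {
  # X = I2, y = (1, -1), theta = sigma2 = 1, mu = 0:
  # (K + I) = 2 I  =>  alpha = (0.5, -0.5); w = alpha; f([1,0]) = 0.5
  X <- diag(2)
  m <- structure(list(theta = 1, sigma2 = 1, mu = 0,
                      alpha = c(0.5, -0.5), n_train = 2, kernel = "linear"),
                 class = "gp_model")
  expect_equal(predict_gpr(m, matrix(c(1, 0), 1)), 0.5)
  expect_equal(reconstruct_weights(m, X), c(0.5, -0.5))
})

test_that("fitted model: constant targets, interpolation limit, orthogonal test points", {
  set.seed(43)
  X <- matrix(rnorm(10 * 4), 10, 4)
  K <- linear_kernel(X)
  m_const <- fit_gpr(K, rep(3.7, 10))
  expect_equal(predict_gpr(m_const, linear_kernel(X[1:2, ], X)),
               c(3.7, 3.7), tolerance = 1e-8)
  # interpolation limit: with sigma2 fixed near zero, a test point equal to
  # a training point reproduces that training target
  y <- as.vector(X %*% c(1, -2, 0.5, 0))
  alpha <- solve(K + diag(1e-12, 10), y)
  m_int <- structure(list(theta = 1, sigma2 = 1e-12, mu = 0, alpha = alpha,
                          n_train = 10), class = "gp_model")
  expect_lt(abs(predict_gpr(m_int, K[3, , drop = FALSE]) - y[3]), 1e-4)
  # a test point orthogonal to all training points predicts mu
  m <- fit_gpr(K, y)
  x_perp <- matrix(0, 1, 4)
  expect_equal(predict_gpr(m, linear_kernel(x_perp, X)), m$mu)
})

test_that("dual and primal predictions agree to 1e-10 on random instances", {
  set.seed(44)
  for (rep in 1:20) {
    n <- sample(5:30, 1); p <- sample(2:50, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    m <- fit_gpr(linear_kernel(X), y)
    w <- reconstruct_weights(m, X)
    Xt <- matrix(rnorm(7 * p), 7, p)
    expect_lt(max(abs(predict_gpr(m, linear_kernel(Xt, X)) -
                        (m$mu + as.vector(Xt %*% w)))), 1e-10)
  }
  # zero dual coefficients give a zero weight map
  m0 <- structure(list(theta = 2, sigma2 = 1, mu = 0, alpha = rep(0, 4),
                       n_train = 4), class = "gp_model")
  expect_equal(reconstruct_weights(m0, matrix(rnorm(12), 4, 3)), rep(0, 3))
})

test_that("GPR with fixed hyperparameters equals primal ridge with penalty sigma2/theta", {
  set.seed(45)
  n <- 12; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  theta <- 0.8; sigma2 <- 0.3
  K <- linear_kernel(X)
  alpha <- solve(theta * K + diag(sigma2, n), y)
  m <- structure(list(theta = theta, sigma2 = sigma2, mu = 0, alpha = alpha,
                      n_train = n), class = "gp_model")
  Xt <- matrix(rnorm(5 * p), 5, p)
  w_ridge <- solve(crossprod(X) + diag(sigma2 / theta, p), crossprod(X, y))
  expect_equal(predict_gpr(m, linear_kernel(Xt, X)),
               as.vector(Xt %*% w_ridge), tolerance = 1e-9)
})

test_that("the fitted evidence dominates random hyperparameter probes", {
  set.seed(46)
  X <- matrix(rnorm(15 * 5), 15, 5)
  K <- linear_kernel(X)
  y <- as.vector(X %*% rnorm(5)) + rnorm(15, sd = 0.5)
  m <- fit_gpr(K, y)
  jit <- 1e-8 * sum(diag(K)) / 15
  probes <- vapply(1:100, function(i) {
    th <- exp(runif(1, -6, 6)); s2 <- exp(runif(1, -6, 6))
    log_marginal_likelihood(K, y, th, s2, m$mu, jitter = jit)
  }, 0)
  expect_gte(m$lml + 1e-6, max(probes))
})

test_that("noise variance is recovered within a factor of 3 (median over seeds)", {
  est <- numeric(20)
  for (s in 1:20) {
    set.seed(700 + s)
    X <- matrix(rnorm(50 * 10), 50, 10) / sqrt(10)
    y <- as.vector(X %*% rnorm(10)) + rnorm(50, sd = 0.1)
    est[s] <- fit_gpr(linear_kernel(X), y)$sigma2
  }
  ratio <- median(est) / 0.01
  expect_gt(ratio, 1 / 3)
  expect_lt(ratio, 3)
})

test_that("GPC separates far clusters and is at chance on noise", {
  acc_sep <- numeric(20)
  for (s in 1:20) {
    set.seed(800 + s)
    n <- 30
    lab <- rep(c("a", "b"), each = n / 2)
    X <- matrix(rnorm(n * 5, sd = 0.3), n, 5) +
      outer(ifelse(lab == "b", 1.5, -1.5), rep(1, 5))
    cl <- cv_gpc_closure(X, folds = rep(1:2, length.out = n))
    acc_sep[s] <- cl(lab)$balanced
  }
  expect_gte(mean(acc_sep >= 0.95), 0.95)
  acc_null <- numeric(30)
  for (s in 1:30) {
    set.seed(900 + s)
    n <- 40
    lab <- rep(c("a", "b"), each = n / 2)
    X <- matrix(rnorm(n * 20), n, 20)
    cl <- cv_gpc_closure(X, folds = rep(1:2, length.out = n))
    acc_null[s] <- cl(sample(lab))$balanced
  }
  expect_gt(median(acc_null), 0.4)
  expect_lt(median(acc_null), 0.6)
})

test_that("GPC probabilities are label-flip antisymmetric and sane on a 1-D toy", {
  X <- matrix(c(-1, 1), 2, 1)
  K <- linear_kernel(X)
  m_pos <- fit_gpc(K, c("neg", "pos"))      # +1 class at x = +1
  p_at_pos <- predict_gpc(m_pos, linear_kernel(matrix(1), X), 1)
  expect_gt(p_at_pos, 0.5)
  m_flip <- fit_gpc(K, c("pos", "neg"))
  p_flip <- predict_gpc(m_flip, linear_kernel(matrix(1), X), 1)
  expect_equal(p_at_pos, 1 - p_flip, tolerance = 1e-6)
  expect_error(fit_gpc(K, c("a", "a")), "2 classes")
})
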
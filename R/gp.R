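# Gaussian-process regression and classification with a linear kernel.
#
# GPR predictive mean with a linear kernel is a linear function of the
# features: f(x*) = mu + theta * k(x*, X) alpha with
# alpha = (theta K + sigma^2 I)^-1 (y - mu), equivalently f(x*) = mu + x* w
# with the primal weights w = theta X^T alpha. Hyperparameters (theta,
# sigma^2) maximize the log marginal likelihood; the constant mean mu is
# fixed at the training-target mean and not co-optimized.
#
# Because the kernel does not depend on (theta, sigma^2), a single symmetric
# eigendecomposition K = U diag(lambda) U^T makes every likelihood
# evaluation O(n): with d = theta*lambda + sigma^2 and z = U^T (y - mu),
#   lml = -1/2 sum(z^2/d) - 1/2 sum(log d) - n/2 log(2 pi).
# Permutation tests refit thousands of models on the same kernel, so this
# is the difference between minutes and hours.

#' Linear kernel (Gram) matrix
#'
#' @param Xa,Xb Numeric matrices with equal feature dimension; `Xb` defaults
#'   to `Xa`.
#' @return `nrow(Xa)` x `nrow(Xb)` matrix of row dot products.
#' @export
linear_kernel <- function(Xa, Xb = Xa) {
  Xa <- as.matrix(Xa); Xb <- as.matrix(Xb)
  if (ncol(Xa) != ncol(Xb))
    stop("feature dimension mismatch: ", ncol(Xa), " vs ", ncol(Xb))
  tcrossprod(Xa, Xb)
}

#' Log marginal likelihood of GPR with fixed hyperparameters
#'
#' Evaluates `-1/2 (y-mu)' (theta K + sigma2 I)^-1 (y-mu)
#' - 1/2 log det(theta K + sigma2 I) - n/2 log(2 pi)` via a Cholesky
#' factorization.
#'
#' @param K Square symmetric kernel matrix.
#' @param y Target vector.
#' @param theta Kernel scale, `> 0`.
#' @param sigma2 Noise variance, `> 0`.
#' @param mu Constant mean.
#' @param jitter Diagonal jitter added before factorization (default 0).
#' @return The log marginal likelihood (scalar).
#' @export
log_marginal_likelihood <- function(K, y, theta, sigma2, mu = 0, jitter = 0) {
  K <- as.matrix(K)
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n, sigma2 > 0, theta > 0)
  C <- theta * K + diag(sigma2 + jitter, n)
  L <- tryCatch(chol(C), error = function(e)
    stop("covariance not positive definite after jitter"))
  r <- y - mu
  v <- backsolve(L, r, transpose = TRUE)
  -0.5 * sum(v^2) - sum(log(diag(L))) - 0.5 * n * log(2 * pi)
}

# Eigendecomposition of K with the package's standard jitter folded into the
# eigenvalues; reusable across hyperparameter evaluations and permutations.
gp_kernel_eigen <- function(K) {
  K <- as.matrix(K)
  n <- nrow(K)
  jit <- 1e-8 * sum(diag(K)) / n
  e <- eigen(K + diag(jit, n), symmetric = TRUE)
  list(values = pmax(e$values, 0), vectors = e$vectors, n = n, jitter = jit)
}

# lml on the eigenbasis, vectorized over a grid of (theta, sigma2) pairs.
.lml_eig <- function(theta, sigma2, lambda, z) {
  n <- length(z)
  D <- outer(lambda, theta) + rep(sigma2, each = n)   # n x n_grid
  -0.5 * colSums(z^2 / D) - 0.5 * colSums(log(D)) - 0.5 * n * log(2 * pi)
}

#' Fit Gaussian-process regression with a linear kernel
#'
#' The constant mean is fixed at the training-target mean. `(theta, sigma2)`
#' maximize the log marginal likelihood over a deterministic log-spaced
#' `grid_size` x `grid_size` grid spanning `[1e-4, 1e4]`, scaled by
#' `var(y)/mean(diag(K))` for `theta` and `var(y)` for `sigma2`, followed by
#' Nelder-Mead refinement in log space. No random restarts: the fit is a
#' deterministic function of `(K, y)`.
#'
#' @param K Training kernel matrix (from [linear_kernel()]).
#' @param y Training targets (length `>= 3`).
#' @param eig Optional precomputed [gp_kernel_eigen()] of `K` (for reuse
#'   across permutations).
#' @param grid_size Grid points per axis (default 20).
#' @param refine Run Nelder-Mead refinement after the grid (default TRUE).
#' @return A `gp_model`: `theta`, `sigma2`, `mu`, `alpha`, `lml`, `n_train`.
#' @export
fit_gpr <- function(K, y, eig = NULL, grid_size = 20L, refine = TRUE) {
  n <- length(y)
  if (n < 3) stop("need at least 3 training subjects")
  if (is.null(eig)) eig <- gp_kernel_eigen(K)
  stopifnot(eig$n == n)
  mu <- mean(y)
  vy <- stats::var(y)
  if (vy == 0) vy <- 1          # constant targets: any scale gives alpha = 0
  kbar <- mean(eig$values)
  if (kbar <= 0) kbar <- 1
  z <- crossprod(eig$vectors, y - mu)[, 1]

  lg <- seq(log(1e-4), log(1e4), length.out = grid_size)
  theta_grid <- exp(lg) * vy / kbar
  sigma2_grid <- exp(lg) * vy
  grid <- expand.grid(theta = theta_grid, sigma2 = sigma2_grid)
  ll <- .lml_eig(grid$theta, grid$sigma2, eig$values, z)
  best <- which.max(ll)
  par <- log(c(grid$theta[best], grid$sigma2[best]))
  val <- ll[best]
  if (refine) {
    negobj <- function(p) -.lml_eig(exp(p[1]), exp(p[2]), eig$values, z)
    opt <- stats::optim(par, negobj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
    if (-opt$value >= val) { par <- opt$par; val <- -opt$value }
  }
  theta <- exp(par[1]); sigma2 <- exp(par[2])
  d <- theta * eig$values + sigma2
  alpha <- eig$vectors %*% (z / d)
  structure(list(theta = theta, sigma2 = sigma2, mu = mu,
                 alpha = as.vector(alpha), lml = val, n_train = n,
                 kernel = "linear"),
            class = "gp_model")
}

#' Predict from a fitted GPR model
#'
#' @param model A [fit_gpr()] result.
#' @param K_test_train Test-by-train kernel matrix (columns in the training
#'   order the model was fitted with).
#' @return Numeric vector of predictive means `mu + theta K* alpha`.
#' @export
predict_gpr <- function(model, K_test_train) {
  K_test_train <- matrix(K_test_train, ncol = model$n_train)
  model$mu + model$theta * as.vector(K_test_train %*% model$alpha)
}

#' Reconstruct primal voxel weights from the dual coefficients
#'
#' `w = theta X_train' alpha`, so that `mu + x* w` reproduces
#' [predict_gpr()] for any test point `x*`.
#'
#' @param model A [fit_gpr()] result.
#' @param X_train The training feature matrix the kernel was computed from.
#' @return Numeric weight vector of length `ncol(X_train)`.
#' @export
reconstruct_weights <- function(model, X_train) {
  X_train <- as.matrix(X_train)
  if (nrow(X_train) != model$n_train)
    stop("X_train rows do not match the training set")
  model$theta * as.vector(crossprod(X_train, model$alpha))
}

# ---------------------------------------------------------------------------
# Gaussian-process classification: probit likelihood, Laplace approximation.

# log Phi(z), phi/Phi ratio, stable in the lower tail.
.probit_ratio <- function(z) exp(stats::dnorm(z, log = TRUE) -
                                   stats::pnorm(z, log.p = TRUE))

# Laplace mode finding (Rasmussen & Williams Alg. 3.1) for fixed covariance C.
.gpc_laplace <- function(C, y, max_iter = 60, tol = 1e-8) {
  n <- length(y)
  f <- numeric(n)
  obj_old <- -Inf
  for (it in seq_len(max_iter)) {
    zy <- y * f
    r <- .probit_ratio(zy)
    grad <- y * r
    W <- r^2 + zy * r
    W <- pmax(W, 1e-12)
    sW <- sqrt(W)
    B <- diag(n) + (sW %o% sW) * C
    L <- chol(B)
    b <- W * f + grad
    v <- backsolve(L, forwardsolve(t(L), sW * (C %*% b)))
    a <- b - sW * v
    f <- as.vector(C %*% a)
    obj <- -0.5 * sum(a * f) + sum(stats::pnorm(y * f, log.p = TRUE))
    if (abs(obj - obj_old) < tol) break
    obj_old <- obj
  }
  zy <- y * f
  r <- .probit_ratio(zy)
  W <- pmax(r^2 + zy * r, 1e-12)
  sW <- sqrt(W)
  L <- chol(diag(n) + (sW %o% sW) * C)
  evidence <- -0.5 * sum(a * f) + sum(stats::pnorm(y * f, log.p = TRUE)) -
    sum(log(diag(L)))
  list(f = f, grad = y * .probit_ratio(y * f), sW = sW, L = L,
       evidence = evidence)
}

#' Fit Gaussian-process classification (probit likelihood, Laplace)
#'
#' Binary GP classifier with linear kernel. The latent posterior is
#' approximated by the Laplace method; the kernel scale `theta` is selected
#' by maximizing the Laplace-approximate marginal likelihood over a
#' deterministic log-spaced grid.
#'
#' @param K Training kernel matrix.
#' @param labels Training labels with exactly two classes; coded internally
#'   as -1/+1 (`sort(unique)`: second level is +1).
#' @param grid_size Number of `theta` grid points (default 15).
#' @return A `gpc_model`: `theta`, `grad` (likelihood gradient at the mode),
#'   `sW`, `L`, `levels`, `n_train`, `evidence`.
#' @export
fit_gpc <- function(K, labels, grid_size = 15L) {
  K <- as.matrix(K)
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2) stop("training labels must contain exactly 2 classes")
  y <- ifelse(as.character(labels) == lev[2], 1, -1)
  n <- length(y)
  stopifnot(nrow(K) == n)
  jit <- 1e-8 * sum(diag(K)) / n
  kbar <- mean(diag(K)); if (kbar <= 0) kbar <- 1
  theta_grid <- exp(seq(log(1e-4), log(1e4), length.out = grid_size)) / kbar
  best <- NULL
  for (theta in theta_grid) {
    C <- theta * K + diag(theta * jit, n)
    fit <- .gpc_laplace(C, y)
    if (is.null(best) || fit$evidence > best$evidence) {
      best <- fit; best$theta <- theta
    }
  }
  structure(list(theta = best$theta, grad = best$grad, sW = best$sW,
                 L = best$L, f_hat = best$f, levels = lev, n_train = n,
                 evidence = best$evidence, kernel = "linear"),
            class = "gpc_model")
}

#' Predictive class probabilities from a fitted GPC model
#'
#' Laplace predictive probability of the positive class (the model's second
#' level): `Phi(fbar / sqrt(1 + var))` with the latent predictive mean
#' `fbar = theta k*' grad` and variance from the Laplace posterior. When
#' `k_test_diag` is omitted the variance correction is skipped and
#' `Phi(fbar)` is returned (probabilities stay on the correct side of 0.5).
#'
#' @param model A [fit_gpc()] result.
#' @param K_test_train Test-by-train kernel matrix.
#' @param k_test_diag Optional vector of test self-kernels `k(x*, x*)`.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_gpc <- function(model, K_test_train, k_test_diag = NULL) {
  K_test_train <- matrix(K_test_train, ncol = model$n_train)
  Ks <- model$theta * K_test_train
  fbar <- as.vector(Ks %*% model$grad)
  if (is.null(k_test_diag)) return(stats::pnorm(fbar))
  v <- forwardsolve(t(model$L), model$sW * t(Ks))
  var_f <- model$theta * k_test_diag - colSums(v^2)
  var_f <- pmax(var_f, 0)
  stats::pnorm(fbar / sqrt(1 + var_f))
}
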
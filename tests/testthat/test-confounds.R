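# Confound screening and train/test-separated removal.

test_that("screening runs the right test per confound type", {
  tab <- data.frame(scanner = rep(c("A", "B"), each = 10),
                    age = 1:20, s1 = 2 * (1:20), s2 = rep(5, 20) + rnorm(20))
  rep <- screen_confounds(tab, scales = c("s1", "s2"),
                          confounds = c("scanner", "age"))
  expect_equal(nrow(rep), 4)
  expect_equal(rep$test[rep$confound == "scanner"], rep("two-sample t", 2))
  # exact linearity: Pearson r = 1
  expect_equal(rep$statistic[rep$confound == "age" & rep$scale == "s1"], 1)
  # identical groups: t = 0, p = 1
  tab2 <- data.frame(g = rep(c("x", "y"), each = 5), s = rep(c(1, 2, 3, 4, 5), 2))
  r2 <- screen_confounds(tab2, "s", "g")
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
  expect_error(screen_confounds(tab, "s1", "missing_col"), "not found")
})

test_that("scanner-linked scores are detected in nearly all seeded cohorts", {
  hits <- logical(100)
  for (s in 1:100) {
    co <- generate_cohort(tiny_config(seed = 300 + s, n_distressed = 40L,
                                      n_healthy = 40L, grid_shape = c(3L, 3L, 3L),
                                      n_signal_voxels = 2L))
    tab <- subject_table(co$records)
    rep <- screen_confounds(tab, "stai_t", "scanner")
    hits[s] <- rep$p_value < 0.05
  }
  # scanner B is mostly distressed, so scanner and STAI-T are associated
  expect_gte(mean(hits), 0.95)
})

test_that("intercept-only model centres columns; perfect-confound columns residualize to zero", {
  set.seed(21)
  X <- matrix(rnorm(30), 6, 5)
  tab <- data.frame(age = rnorm(6))
  m0 <- fit_confound_model(X, tab, character(0))
  expect_equal(as.vector(m0$coefficients), colMeans(X))
  X2 <- cbind(X, tab$age)
  m <- fit_confound_model(X2, tab, "age")
  res <- remove_confounds(m, X2, tab)
  expect_lt(max(abs(res[, 6])), 1e-10)
})

test_that("coefficients match an explicit normal-equations oracle", {
  set.seed(22)
  X <- matrix(rnorm(6 * 4), 6, 4)
  tab <- data.frame(age = rnorm(6), iq = rnorm(6))
  m <- fit_confound_model(X, tab, c("age", "iq"))
  # oracle: standardize as the model does, then solve (D'D)^-1 D'X densely
  D <- cbind(1, (tab$age - mean(tab$age)) / sd(tab$age),
             (tab$iq - mean(tab$iq)) / sd(tab$iq))
  B <- solve(t(D) %*% D) %*% t(D) %*% X
  expect_lt(max(abs(unname(m$coefficients) - B)), 1e-10)
})

test_that("training residuals are orthogonal to the design; removal is idempotent", {
  set.seed(23)
  X <- matrix(rnorm(40 * 7), 40, 7)
  tab <- data.frame(age = rnorm(40), scanner = sample(c("A", "B"), 40, TRUE))
  m <- fit_confound_model(X, tab, c("age", "scanner"))
  res <- remove_confounds(m, X, tab)
  D <- cbind(1, (tab$age - mean(tab$age)) / sd(tab$age),
             as.numeric(tab$scanner == "B"))
  expect_lt(max(abs(t(D) %*% res)), 1e-9)
  res2 <- remove_confounds(fit_confound_model(res, tab, c("age", "scanner")),
                           res, tab)
  expect_lt(max(abs(res2 - res)), 1e-10)
})

test_that("test-row residuals keep using training coefficients (and are not re-orthogonalized)", {
  # rig: the feature-confound slope differs between training (2) and test
  # (5) rows, so training coefficients cannot orthogonalize the test rows
  set.seed(24)
  n_tr <- 30; n_te <- 10
  age_tr <- rnorm(n_tr); age_te <- rnorm(n_te)
  X_tr <- matrix(2 * age_tr + rnorm(n_tr * 3, sd = 0.1), n_tr, 3)
  X_te <- matrix(5 * age_te + rnorm(n_te * 3, sd = 0.1), n_te, 3)
  m <- fit_confound_model(X_tr, data.frame(age = age_tr), "age")
  res_te <- remove_confounds(m, X_te, data.frame(age = age_te))
  # residuals on shifted test rows are NOT orthogonal to the test confound
  expect_gt(abs(sum((age_te - mean(age_te)) * res_te[, 1])), 1)
  # zeroed coefficients give the identity
  m$coefficients[] <- 0
  expect_identical(remove_confounds(m, X_te, data.frame(age = age_te)), X_te)
})

test_that("rank-deficient or mismatched designs are rejected", {
  X <- matrix(rnorm(20), 5, 4)
  tab <- data.frame(a = rep(1, 5), b = rnorm(5))
  expect_error(fit_confound_model(X, tab, c("b", "b")), "rank")
  m <- fit_confound_model(X, tab, "b")
  expect_error(remove_confounds(m, X, data.frame(c = rnorm(5))), "not found")
})

test_that("leakage sentinel: per-fold confound removal adds no bias beyond the intrinsic CV offset", {
  # Null features, confound strongly associated with the target. The
  # implemented per-fold removal must sit on the same small negative offset
  # that concatenated CV r has for *any* null predictor at this n (the
  # fold-mean anticorrelation effect) — i.e. removal itself leaks nothing.
  # Targets are never residualized anywhere in the package (no API for it).
  n <- 154; p <- 400
  r_pkg <- r_plain <- numeric(60)
  for (s in 1:60) {
    set.seed(4000 + s)
    age <- rnorm(n)
    y <- 0.8 * age + rnorm(n)
    X <- matrix(rnorm(n * p), n, p)
    folds <- rep(1:2, length.out = n)
    r_pkg[s] <- cv_gpr_closure(X, data.frame(age = age), folds,
                               confounds = "age")(y)$r
    r_plain[s] <- cv_gpr_closure(X, NULL, folds,
                                 confounds = character(0))(y)$r
  }
  expect_lt(abs(mean(r_pkg)), 0.1)
  expect_lt(abs(mean(r_pkg) - mean(r_plain)), 0.05)
})
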
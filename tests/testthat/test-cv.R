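# Fold construction and the cross-validated fit/predict loop.

test_that("154 subjects split 2-fold into (77, 77) with scanner balance", {
  tab <- fold_test_table(seed = 31)
  folds <- make_balanced_folds(tab, 2, target = "stai_t", seed = 1)
  expect_equal(sort(folds$sizes), c(77, 77))
  expect_s3_class(folds, "fold_assignment")
  # every subject in exactly one fold
  expect_equal(sort(unique(folds$fold)), 1:2)
  expect_length(folds$fold, 154)
})

test_that("k=5 spreads the 35 scanner-B subjects as 7 per fold and passes the target t-tests", {
  tab <- fold_test_table(seed = 32)
  folds <- make_balanced_folds(tab, 5, target = "stai_t", seed = 2)
  expect_true(max(folds$sizes) - min(folds$sizes) <= 1)
  b_counts <- table(folds$fold[tab$scanner == "B"])
  expect_equal(unname(as.vector(b_counts)), rep(7, 5))
  # recompute every pairwise Welch t-test on the emitted assignment
  for (i in 1:4) for (j in (i + 1):5) {
    p <- t.test(tab$stai_t[folds$fold == i],
                tab$stai_t[folds$fold == j])$p.value
    expect_gt(p, 0.05)
  }
})

test_that("leave-one-out is allowed and skips the vacuous checks", {
  tab <- fold_test_table(10, 10, 3, 2, seed = 33)
  folds <- make_balanced_folds(tab, 20, target = "stai_t", seed = 3)
  expect_equal(sort(folds$sizes), rep(1L, 20))
})

test_that("infeasible balance and exhausted retries raise", {
  tab <- fold_test_table(10, 10, 3, 2, seed = 34)
  expect_error(make_balanced_folds(tab, 8, target = "stai_t", seed = 4),
               "infeasible")
  # impossible acceptance: alpha = 1 demands p > 1
  expect_error(make_balanced_folds(tab, 2, target = "stai_t", alpha = 1,
                                   max_tries = 5, seed = 5), "max_tries")
})

test_that("fold assignment is reproducible under a fixed seed", {
  tab <- fold_test_table(seed = 35)
  f1 <- make_balanced_folds(tab, 5, target = "stai_t", seed = 77)
  f2 <- make_balanced_folds(tab, 5, target = "stai_t", seed = 77)
  expect_identical(f1$fold, f2$fold)
})

test_that("the mean-predictor stub predicts the other fold's training mean", {
  set.seed(36)
  X <- matrix(rnorm(12 * 4), 12, 4)
  y <- rnorm(12)
  fold <- rep(1:2, each = 6)
  res <- run_cv(X, y, folds = fold, model_spec = "mean")
  expect_equal(res$predicted[fold == 1], rep(mean(y[fold == 2]), 6))
  expect_equal(res$predicted[fold == 2], rep(mean(y[fold == 1]), 6))
  expect_identical(res$actual, y)
})

test_that("permuting subject order permutes the predictions identically", {
  set.seed(37)
  n <- 20
  X <- matrix(rnorm(n * 6), n, 6)
  y <- rnorm(n)
  fold <- rep(1:2, length.out = n)
  res <- run_cv(X, y, folds = fold, model_spec = "gpr")
  perm <- sample(n)
  res_p <- run_cv(X[perm, ], y[perm], folds = fold[perm], model_spec = "gpr")
  expect_equal(res_p$predicted, res$predicted[perm], tolerance = 1e-10)
})

test_that("no leakage: a fold's model is unchanged when its test rows are corrupted", {
  set.seed(38)
  n <- 16
  X <- matrix(rnorm(n * 5), n, 5)
  y <- rnorm(n)
  fold <- rep(1:2, each = 8)
  res <- run_cv(X, y, folds = fold, model_spec = "gpr")
  X_bad <- X
  X_bad[fold == 2, ] <- 1e6 * matrix(rnorm(8 * 5), 8, 5)
  res_bad <- run_cv(X_bad, y, folds = fold, model_spec = "gpr")
  # fold 2's model is trained on fold 1 only, so corrupting fold-2 rows
  # cannot change it
  expect_equal(res_bad$fold_models[[2]]$weights,
               res$fold_models[[2]]$weights, tolerance = 1e-12)
  expect_equal(res_bad$fold_models[[2]]$theta, res$fold_models[[2]]$theta)
})

test_that("run_cv and the precompiled closure produce identical predictions", {
  co <- generate_cohort(tiny_config(seed = 39))
  tab <- subject_table(co$records)
  vols <- lapply(co$records, `[[`, "volume")
  mask <- build_common_mask(vols)
  feats <- assemble_features(vols, mask, ids = tab$subject_id)
  folds <- make_balanced_folds(tab, 2, target = "stai_t", seed = 6)
  res <- run_cv(feats, tab$stai_t, tab, folds, confounds = "age",
                model_spec = "gpr")
  cl <- cv_gpr_closure(feats, tab, folds, confounds = "age")
  expect_equal(cl(tab$stai_t)$predicted, res$predicted, tolerance = 1e-8)
})

test_that("cross-validated r sits in the null band on signal-free cohorts", {
  inside <- logical(60)
  for (s in 1:60) {
    cfg <- null_config(seed = 500 + s, grid_shape = c(8L, 8L, 8L))
    co <- generate_cohort(cfg)
    tab <- subject_table(co$records)
    X <- t(vapply(co$records, function(r) as.vector(r$volume), numeric(512)))
    folds <- make_balanced_folds(tab, 2, target = "stai_t", seed = 600 + s)
    cl <- cv_gpr_closure(X, tab, folds, confounds = "age")
    inside[s] <- abs(cl(tab$stai_t)$r) < 2 / sqrt(154)
  }
  expect_gte(mean(inside), 0.85)
})
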
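# Scanner-balanced cross-validation and the fit/predict loop.
#
# Fold construction mechanizes "manual balancing": seeded rejection sampling
# deals each balance-key stratum round-robin across folds (so scanner
# proportions are as even as integer divisibility allows), then accepts the
# assignment only if fold sizes differ by at most one and all pairwise
# two-sample t-tests on the target scale across folds have p > alpha.

#' Build scanner-balanced, distribution-checked k folds
#'
#' @param table Subject `data.frame`.
#' @param k Number of folds, `2 <= k <= n`. With `k = n` (leave-one-out) the
#'   balance and t-test checks are vacuous and skipped.
#' @param target Column name of the scale being decoded; fold pairs must not
#'   differ on it (Welch t-test, `p > alpha`). `NULL` skips the check.
#' @param balance_keys Character vector of categorical columns to stratify
#'   on (default `"scanner"`). Each level must have at least `k` members
#'   (unless `k = n`).
#' @param alpha Acceptance level for the fold t-tests (default 0.05).
#' @param max_tries Rejection-sampling budget (default 10000).
#' @param seed Integer seed; the assignment is deterministic given
#'   `(table, k, seed)`. `NULL` uses the current RNG state.
#' @return A `fold_assignment`: `fold` (integer in `1..k` per subject, input
#'   order), `k`, `sizes`, `balance` (per-fold balance-key counts),
#'   `target_tests` (pairwise t-test p-values), `tries`.
#' @export
make_balanced_folds <- function(table, k, target = NULL,
                                balance_keys = "scanner", alpha = 0.05,
                                max_tries = 10000L, seed = NULL) {
  n <- nrow(table)
  k <- as.integer(k)
  if (k < 2 || k > n) stop("k must be in 2..n")
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
  }
  y <- if (is.null(target)) NULL else {
    v <- table[[target]]
    if (is.null(v)) stop("target column not found: ", target)
    v
  }
  strata <- if (length(balance_keys)) {
    for (b in balance_keys) if (is.null(table[[b]]))
      stop("balance key column not found: ", b)
    interaction(table[balance_keys], drop = TRUE)
  } else factor(rep(1L, n))
  # feasibility is judged per key level (a scanner with < k subjects cannot
  # be represented in every fold); joint strata may legitimately be smaller
  if (k < n) for (b in balance_keys) {
    cnt <- table(table[[b]])
    if (any(cnt < k))
      stop("infeasible balance: level '", names(which(cnt < k))[1], "' of '",
           b, "' has fewer than k members")
  }

  sizes_target <- rep(n %/% k, k)
  if (n %% k > 0) sizes_target[seq_len(n %% k)] <- sizes_target[seq_len(n %% k)] + 1L

  pair_idx <- if (k >= 2) utils::combn(k, 2) else NULL
  for (try in seq_len(max_tries)) {
    fold <- integer(n)
    for (s in levels(strata)) {
      idx <- sample(which(strata == s))
      fold[idx] <- 1L + (sample.int(k, 1L) + seq_along(idx) - 2L) %% k
    }
    sizes <- tabulate(fold, k)
    if (max(sizes) - min(sizes) > 1L) next
    # t-test acceptance check on the target scale
    pvals <- NULL
    ok <- TRUE
    if (!is.null(y) && k < n) {
      pvals <- matrix(NA_real_, k, k)
      for (pc in seq_len(ncol(pair_idx))) {
        i <- pair_idx[1, pc]; j <- pair_idx[2, pc]
        yi <- y[fold == i]; yj <- y[fold == j]
        if (length(yi) < 2 || length(yj) < 2) next  # singleton folds: skip
        if (stats::sd(yi) == 0 && stats::sd(yj) == 0) next
        p <- stats::t.test(yi, yj)$p.value
        pvals[i, j] <- pvals[j, i] <- p
        if (p <= alpha) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    balance <- table(fold = fold, strata)
    return(structure(list(fold = fold, k = k, sizes = sizes,
                          balance = balance, target_tests = pvals,
                          alpha = alpha, tries = try),
                     class = "fold_assignment"))
  }
  stop("max_tries (", max_tries, ") exhausted without a balanced assignment")
}

# Resolve a model spec into fit/predict functions operating on feature rows.
.resolve_model_spec <- function(model_spec, ...) {
  if (is.list(model_spec) && all(c("fit", "predict") %in% names(model_spec)))
    return(model_spec)
  if (identical(model_spec, "gpr")) {
    dots <- list(...)
    return(list(
      fit = function(X_train, y_train) {
        K <- linear_kernel(X_train)
        m <- fit_gpr(K, y_train,
                     grid_size = if (is.null(dots$grid_size)) 20L else dots$grid_size,
                     refine = if (is.null(dots$refine)) TRUE else dots$refine)
        m$weights <- reconstruct_weights(m, X_train)
        m$X_train <- X_train
        m
      },
      predict = function(m, X_test)
        predict_gpr(m, linear_kernel(X_test, m$X_train))))
  }
  if (identical(model_spec, "mean")) {
    return(list(fit = function(X_train, y_train) list(mu = mean(y_train)),
                predict = function(m, X_test) rep(m$mu, nrow(X_test))))
  }
  stop("unknown model_spec; use 'gpr', 'mean', or list(fit=, predict=)")
}

#' Run the cross-validated fit/predict loop
#'
#' Per fold: fit the confound model on the training rows, residualize
#' training and test features with those training-derived parameters, fit
#' the model on training rows, predict the held-out rows. Predictions are
#' concatenated across folds and returned in the original subject order.
#'
#' @param features A `feature_matrix` (see [assemble_features()]) or plain
#'   numeric matrix (subjects x voxels).
#' @param targets Numeric target vector (one per subject).
#' @param table Subject `data.frame` providing confound columns; may be
#'   `NULL` when `confounds` is empty.
#' @param folds A [make_balanced_folds()] result (or an integer fold vector).
#' @param confounds Character vector of confound column names (default
#'   empty: intercept-only centring).
#' @param model_spec `"gpr"` (default), `"mean"` (predicts the training-target
#'   mean; a stub for testing the loop), or `list(fit =, predict =)`.
#' @param ... Passed to the model spec resolver (e.g. `grid_size`, `refine`).
#' @return A `prediction_result`: `predicted`, `actual`, `fold` (test-fold
#'   id per subject, original order), and `fold_models` (per-fold fitted
#'   state, including `weights` for GPR).
#' @export
run_cv <- function(features, targets, table = NULL, folds,
                   confounds = character(0), model_spec = "gpr", ...) {
  X <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  fold <- if (inherits(folds, "fold_assignment")) folds$fold else as.integer(folds)
  n <- nrow(X)
  stopifnot(length(targets) == n, length(fold) == n)
  if (length(confounds) && (is.null(table) || nrow(table) != n))
    stop("confound removal requires a subject table with one row per subject")
  ks <- sort(unique(fold))
  spec <- .resolve_model_spec(model_spec, ...)

  predicted <- rep(NA_real_, n)
  fold_models <- vector("list", length(ks))
  for (fi in seq_along(ks)) {
    f <- ks[fi]
    te <- which(fold == f); tr <- which(fold != f)
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (length(confounds)) {
      cm <- fit_confound_model(Xtr, table[tr, , drop = FALSE], confounds)
      Xtr <- remove_confounds(cm, Xtr, table[tr, , drop = FALSE])
      Xte <- remove_confounds(cm, Xte, table[te, , drop = FALSE])
    }
    m <- tryCatch(spec$fit(Xtr, targets[tr]),
                  error = function(e) stop("fold ", f, ": ", conditionMessage(e)))
    predicted[te] <- tryCatch(spec$predict(m, Xte),
                              error = function(e) stop("fold ", f, ": ",
                                                       conditionMessage(e)))
    m$X_train <- NULL             # drop bulky state before returning
    fold_models[[fi]] <- m
  }
  if (anyNA(predicted)) stop("internal error: some subjects never predicted")
  structure(list(predicted = predicted, actual = as.numeric(targets),
                 fold = fold, fold_models = fold_models),
            class = "prediction_result")
}

#' Precompiled cross-validated GPR closure for permutation testing
#'
#' Confound residualization and the linear kernel depend only on features
#' and confounds — not on the targets — so for a fixed fold assignment the
#' per-fold residualized kernels and their eigendecompositions can be
#' computed once and reused for every permuted target vector. The returned
#' closure runs the exact fit/predict procedure of [run_cv()] (training-fold
#' confound refit included, by precomputation) for an arbitrary target
#' vector, in O(n * grid) per fold instead of O(n^3 * grid).
#'
#' @inheritParams run_cv
#' @param grid_size,refine Passed to [fit_gpr()].
#' @return Function `f(targets)` returning a list with `predicted`,
#'   `actual`, `r` (Pearson correlation) and `nmse` (normalized MSE; `NA`
#'   if the predictions are constant).
#' @export
cv_gpr_closure <- function(features, table = NULL, folds,
                           confounds = character(0), grid_size = 20L,
                           refine = TRUE) {
  X <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  fold <- if (inherits(folds, "fold_assignment")) folds$fold else as.integer(folds)
  n <- nrow(X)
  ks <- sort(unique(fold))
  pre <- lapply(ks, function(f) {
    te <- which(fold == f); tr <- which(fold != f)
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (length(confounds)) {
      cm <- fit_confound_model(Xtr, table[tr, , drop = FALSE], confounds)
      Xtr <- remove_confounds(cm, Xtr, table[tr, , drop = FALSE])
      Xte <- remove_confounds(cm, Xte, table[te, , drop = FALSE])
    }
    K <- linear_kernel(Xtr)
    list(tr = tr, te = te, eig = gp_kernel_eigen(K),
         K_te_tr = linear_kernel(Xte, Xtr))
  })
  function(targets) {
    stopifnot(length(targets) == n)
    predicted <- rep(NA_real_, n)
    for (p in pre) {
      m <- fit_gpr(K = NULL, y = targets[p$tr], eig = p$eig,
                   grid_size = grid_size, refine = refine)
      predicted[p$te] <- predict_gpr(m, p$K_te_tr)
    }
    r <- if (stats::sd(predicted) > 0 && stats::sd(targets) > 0)
      stats::cor(predicted, targets) else NA_real_
    nmse <- if (max(predicted) > min(predicted))
      normalized_mse(predicted, targets) else NA_real_
    list(predicted = predicted, actual = as.numeric(targets),
         r = r, nmse = nmse)
  }
}
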
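# Agreement metrics, classification metrics, permutation inference, and
# Bonferroni control.

#' Pearson correlation between predicted and actual scores
#'
#' @param predicted,actual Numeric vectors of equal length `>= 3`, both
#'   non-constant.
#' @return Sample Pearson correlation in `[-1, 1]`.
#' @export
pearson_r <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  if (length(predicted) < 3) stop("need at least 3 pairs")
  if (stats::sd(predicted) == 0 || stats::sd(actual) == 0)
    stop("constant input: correlation undefined")
  stats::cor(predicted, actual)
}

#' Normalized mean squared error
#'
#' The mean of the squared prediction errors divided by the *range of the
#' predictions* (max minus min). Note the asymmetry: the denominator is the
#' predicted range, not the actual range, so
#' `normalized_mse(a, b) != normalized_mse(b, a)` in general.
#'
#' @param predicted Numeric predictions; must be non-constant (a zero range
#'   is an error, never an infinity).
#' @param actual Numeric true scores.
#' @return Nonnegative scalar.
#' @export
normalized_mse <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  rng <- max(predicted) - min(predicted)
  if (rng == 0) stop("constant predictions: normalized MSE undefined")
  mean((predicted - actual)^2) / rng
}

#' Balanced accuracy and per-class accuracies
#'
#' @param truth True class labels (both classes must be present).
#' @param predicted Predicted class labels on the same coding.
#' @return List with `balanced` (mean of the per-class accuracies) and
#'   `per_class` (named vector of within-class accuracies).
#' @export
balanced_accuracy <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop("length mismatch")
  lev <- sort(unique(truth))
  if (length(lev) != 2) stop("need exactly 2 classes in the true labels")
  per <- vapply(lev, function(l) mean(predicted[truth == l] == l), 0)
  list(balanced = mean(per), per_class = per)
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_scales Number of scales tested.
#' @param n_cv_schemes Number of cross-validation schemes.
#' @param alpha Family-wise level (default 0.05).
#' @return `alpha / (n_scales * n_cv_schemes)`.
#' @export
bonferroni_threshold <- function(n_scales, n_cv_schemes, alpha = 0.05) {
  stopifnot(n_scales >= 1, n_cv_schemes >= 1)
  alpha / (n_scales * n_cv_schemes)
}

#' Permutation test of cross-validated prediction performance
#'
#' Repeats the full cross-validated procedure on seeded uniform shuffles of
#' the target vector (folds held fixed; confound handling is re-applied
#' inside the closure) and counts permutations at least as extreme as the
#' observed statistic:
#' `p_r = #{perm : |r_perm| >= |r_obs|} / n_permutations` and
#' `p_mse = #{perm : mse_perm <= mse_obs} / n_permutations` (signed, lower
#' is better for MSE). These literal count/n p-values can reach 0; the
#' conservative `(count+1)/(n+1)` versions are reported alongside.
#'
#' @param pipeline Closure mapping a target vector to a list with elements
#'   `r` and `nmse` (see [cv_gpr_closure()]). Permutations for which the
#'   closure returns `NA` (e.g. degenerate constant predictions) are
#'   counted as exceedances — the conservative direction.
#' @param targets Observed target vector.
#' @param n_permutations Number of shuffles (default 1000).
#' @param seed Integer seed for the shuffles.
#' @param observed Optional precomputed `pipeline(targets)` result.
#' @return A `permutation_result`: `observed` (list `r`, `nmse`), `null_r`,
#'   `null_mse`, `p_r`, `p_mse`, `p_r_conservative`, `p_mse_conservative`,
#'   `n_permutations`, `seed`.
#' @export
permutation_test <- function(pipeline, targets, n_permutations = 1000L,
                             seed = 1L, observed = NULL) {
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (is.null(observed)) observed <- pipeline(targets)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  null_r <- numeric(n_permutations)
  null_mse <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    res <- pipeline(sample(targets))
    null_r[b] <- res$r
    null_mse[b] <- res$nmse
  }
  cnt_r <- sum(is.na(null_r) | abs(null_r) >= abs(observed$r))
  cnt_mse <- sum(is.na(null_mse) | null_mse <= observed$nmse)
  structure(list(observed = observed, null_r = null_r, null_mse = null_mse,
                 p_r = cnt_r / n_permutations,
                 p_mse = cnt_mse / n_permutations,
                 p_r_conservative = (cnt_r + 1) / (n_permutations + 1),
                 p_mse_conservative = (cnt_mse + 1) / (n_permutations + 1),
                 n_permutations = n_permutations, seed = seed),
            class = "permutation_result")
}

#' Permutation test for classification (label shuffles)
#'
#' Same machinery as [permutation_test()] for a balanced-accuracy closure:
#' `p = #{perm : ba_perm >= ba_obs} / n_permutations`.
#'
#' @param pipeline Closure mapping a label vector to a list with element
#'   `balanced` (and optionally `per_class`).
#' @param labels Observed class labels.
#' @inheritParams permutation_test
#' @return List with `observed`, `null_balanced`, `p_balanced`,
#'   `p_balanced_conservative`, `n_permutations`, `seed`.
#' @export
permutation_test_classification <- function(pipeline, labels,
                                            n_permutations = 1000L, seed = 1L,
                                            observed = NULL) {
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (is.null(observed)) observed <- pipeline(labels)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  null_ba <- vapply(seq_len(n_permutations),
                    function(b) pipeline(sample(labels))$balanced, 0)
  cnt <- sum(null_ba >= observed$balanced)
  list(observed = observed, null_balanced = null_ba,
       p_balanced = cnt / n_permutations,
       p_balanced_conservative = (cnt + 1) / (n_permutations + 1),
       n_permutations = n_permutations, seed = seed)
}
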
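# Independent brute-force oracles, kept free of the package's own code paths.

# Exhaustive per-subject exclusion decision: loop over every voxel.
oracle_exclude <- function(volumes, scope_arr, max_nan_fraction) {
  vapply(volumes, function(v) {
    n_scope <- 0L; n_bad <- 0L
    for (i in seq_along(scope_arr)) {
      if (scope_arr[i]) {
        n_scope <- n_scope + 1L
        if (!is.finite(v[i])) n_bad <- n_bad + 1L
      }
    }
    n_bad / n_scope <= max_nan_fraction
  }, logical(1))
}

# Exhaustive common-mask membership: a voxel survives iff in scope and
# finite in every subject.
oracle_common_mask <- function(volumes, scope_arr) {
  out <- array(FALSE, dim(scope_arr))
  for (i in seq_along(scope_arr)) {
    if (!scope_arr[i]) next
    ok <- TRUE
    for (v in volumes) if (!is.finite(v[i])) { ok <- FALSE; break }
    out[i] <- ok
  }
  out
}

# Dense log marginal likelihood via explicit inverse and determinant.
oracle_lml <- function(K, y, theta, sigma2, mu) {
  C <- theta * K + diag(sigma2, length(y))
  r <- y - mu
  as.numeric(-0.5 * t(r) %*% solve(C) %*% r - 0.5 * log(det(C)) -
               length(y) / 2 * log(2 * pi))
}
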
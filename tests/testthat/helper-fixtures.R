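# Shared fixtures: all test data is generated in code at run time.

# Small cohort config used where only structure (not power) matters.
tiny_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_distressed = 8L, n_healthy = 8L, grid_shape = c(6L, 6L, 6L),
         n_signal_voxels = 20L, seed = seed),
    list(...))
  do.call(cohort_config, args)
}

# Fully null cohort world: no score-linked signal and no scanner offset, so
# contrast maps are independent of every score (the scanner offset would
# otherwise couple maps to scores through the group/scanner composition).
null_config <- function(seed = 1L, ...) {
  cohort_config(signal_snr = 0, scanner_offset_sd = 0, dropout_fraction = 0,
                seed = seed, ...)
}

# Random volumes with a prescribed NaN pattern (list of linear index vectors).
volumes_with_nans <- function(n, dims, nan_idx = vector("list", n),
                              seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    v <- array(stats::rnorm(prod(dims)), dims)
    if (length(nan_idx[[i]])) v[nan_idx[[i]]] <- NaN
    v
  })
}

# Subject table shaped like the emulated cohort (for fold tests that do not
# need volumes): scanner split 119/35, STAI-T drawn per group.
fold_test_table <- function(n_distressed = 82L, n_healthy = 72L,
                            b_distressed = 32L, b_healthy = 3L, seed = 1L) {
  set.seed(seed)
  n <- n_distressed + n_healthy
  group <- c(rep("distressed", n_distressed), rep("healthy", n_healthy))
  scanner <- c(sample(c(rep("A", n_distressed - b_distressed),
                        rep("B", b_distressed))),
               sample(c(rep("A", n_healthy - b_healthy),
                        rep("B", b_healthy))))
  stai <- ifelse(group == "distressed", stats::rnorm(n, 54.9, 11),
                 stats::rnorm(n, 30.6, 5.7))
  data.frame(subject_id = sprintf("s%03d", seq_len(n)), group = group,
             scanner = scanner, age = stats::rnorm(n, 21.6, 2),
             stai_t = stai, stringsAsFactors = FALSE)
}
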
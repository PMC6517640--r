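# Synthetic cohort generator.
#
# Emulates the statistical structure of the two-scanner distressed/healthy
# young-adult cohort the decoding pipeline was built for: per-group score
# distributions with zero-inflated clinician scales, an unbalanced scanner
# split whose group composition induces scanner-score associations in the
# whole sample (but not within groups), a gender-score shift, frontal
# signal-dropout NaN patches, and a low-SNR, spatially distributed
# score-linked signal embedded in the contrast maps.

#' Cohort configuration
#'
#' @param n_distressed,n_healthy Group sizes (defaults: the 82/72 composition
#'   of the cohort the pipeline emulates).
#' @param grid_shape Integer length-3 voxel grid (default `c(12, 13, 13)`,
#'   2028 voxels — a desk-scale stand-in for a whole-brain grid).
#' @param signal_snr Per-signal-voxel ratio of score-linked signal SD to noise
#'   SD. 0 disables the signal. Default 0.1: a low-SNR, spatially distributed
#'   pattern only detectable multivariately.
#' @param n_signal_voxels Number of voxels carrying the score-linked signal
#'   (default 100). Ignored when `signal_voxels` is supplied.
#' @param signal_voxels Optional explicit linear voxel indices for the signal
#'   (e.g. to confine it to known atlas regions); must avoid the dropout
#'   octant if dropout is enabled and signal voxels should survive masking.
#' @param scanner_split Named list with integer vectors `distressed = c(A=, B=)`
#'   and `healthy = c(A=, B=)`. Default: proportional to the 50/32 and 69/3
#'   split of the emulated cohort (119 vs 35 overall at default sizes).
#' @param dropout_fraction Fraction of subjects receiving a NaN dropout patch.
#' @param dropout_extent Fraction of all voxels NaN in an affected volume; the
#'   patch is a fixed contiguous block in the designated "frontal" octant
#'   (low-index corner), so it must not exceed that octant's share of voxels.
#' @param noise_sd I.i.d. Gaussian voxel noise SD (default 1; the contrast
#'   maps' unit).
#' @param scanner_offset_sd SD of the additive per-voxel scanner-B offset map
#'   (default 0.5, half the noise SD — scanner differences are strong enough
#'   to be decodable but do not swamp the signal).
#' @param gender_offset_sd Female score-mean shift in target-SD units applied
#'   to STAI-T, MASQ-D and HAM-A (default 0.25).
#' @param score_correlation Latent Gaussian-copula correlation among the five
#'   scales (default 0.7).
#' @param primary_scale Scale generating the brain signal (default
#'   `"STAI-T"`).
#' @param female_fraction Probability a subject is female (default 103/154).
#' @param age_mean,age_sd,age_range Age distribution (truncated normal;
#'   defaults 21.6, 2.0, 18-25).
#' @param seed Integer RNG seed; the whole cohort is a deterministic function
#'   of the config.
#' @return A validated `cohort_config` object (a named list).
#' @export
cohort_config <- function(n_distressed = 82L, n_healthy = 72L,
                          grid_shape = c(12L, 13L, 13L),
                          signal_snr = 0.1, n_signal_voxels = 100L,
                          signal_voxels = NULL,
                          scanner_split = NULL,
                          dropout_fraction = 0.2, dropout_extent = 0.05,
                          noise_sd = 1, scanner_offset_sd = 0.5,
                          gender_offset_sd = 0.25, score_correlation = 0.7,
                          primary_scale = "STAI-T",
                          female_fraction = 103 / 154,
                          age_mean = 21.6, age_sd = 2.0, age_range = c(18, 25),
                          seed = 1L) {
  stopifnot(n_distressed >= 1, n_healthy >= 1,
            length(grid_shape) == 3, all(grid_shape >= 2),
            signal_snr >= 0, dropout_fraction >= 0, dropout_fraction <= 1,
            dropout_extent >= 0, dropout_extent <= 1,
            noise_sd > 0, score_correlation >= 0, score_correlation < 1)
  grid_shape <- as.integer(grid_shape)
  n_vox <- prod(grid_shape)
  if (is.null(scanner_split)) {
    b_d <- round(n_distressed * 32 / 82)
    b_h <- round(n_healthy * 3 / 72)
    scanner_split <- list(
      distressed = c(A = n_distressed - b_d, B = b_d),
      healthy    = c(A = n_healthy - b_h, B = b_h))
  }
  for (grp in c("distressed", "healthy")) {
    sp <- scanner_split[[grp]]
    if (is.null(sp) || !all(c("A", "B") %in% names(sp)) || any(sp < 0))
      stop("scanner_split$", grp, " must be a named vector c(A=, B=) >= 0")
    n_grp <- if (grp == "distressed") n_distressed else n_healthy
    if (sum(sp) != n_grp)
      stop("scanner_split$", grp, " sums to ", sum(sp), ", expected ", n_grp)
  }
  if (is.null(signal_voxels)) {
    if (n_signal_voxels > n_vox)
      stop("n_signal_voxels exceeds the number of voxels")
  } else {
    signal_voxels <- as.integer(signal_voxels)
    if (any(signal_voxels < 1 | signal_voxels > n_vox))
      stop("signal_voxels out of range")
    n_signal_voxels <- length(signal_voxels)
  }
  octant_frac <- prod(ceiling(grid_shape / 2)) / n_vox
  if (dropout_fraction > 0 && dropout_extent > octant_frac)
    stop(sprintf("dropout_extent %.3f exceeds the frontal octant's share %.3f",
                 dropout_extent, octant_frac))
  structure(list(
    n_distressed = as.integer(n_distressed), n_healthy = as.integer(n_healthy),
    grid_shape = grid_shape, signal_snr = signal_snr,
    n_signal_voxels = as.integer(n_signal_voxels),
    signal_voxels = signal_voxels, scanner_split = scanner_split,
    dropout_fraction = dropout_fraction, dropout_extent = dropout_extent,
    noise_sd = noise_sd, scanner_offset_sd = scanner_offset_sd,
    gender_offset_sd = gender_offset_sd, score_correlation = score_correlation,
    primary_scale = primary_scale, female_fraction = female_fraction,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    seed = as.integer(seed)), class = "cohort_config")
}

# Linear indices of the fixed "frontal" octant (low-index corner box).
.frontal_octant_indices <- function(grid_shape) {
  half <- ceiling(grid_shape / 2)
  arr <- array(FALSE, grid_shape)
  arr[seq_len(half[1]), seq_len(half[2]), seq_len(half[3])] <- TRUE
  which(arr)
}

# Correlated score draw for one group via a Gaussian copula over the five
# scales; marginals are the calibrated truncated normals (with zero
# inflation folded in), so draw_scores()' marginal law is preserved.
.draw_group_scores <- function(specs, group, n, rho, female, gender_offset_sd) {
  nm <- names(specs)
  p <- length(nm)
  R <- matrix(rho, p, p); diag(R) <- 1
  L <- chol(R)
  z <- matrix(stats::rnorm(n * p), n, p) %*% L
  u <- stats::pnorm(z)
  shift_scales <- c("STAI-T", "MASQ-D", "HAM-A")
  out <- matrix(NA_real_, n, p, dimnames = list(NULL, nm))
  for (j in seq_len(p)) {
    sp <- specs[[nm[j]]][[group]]
    par <- .scale_parent_params(sp)
    mu <- rep(par$mu, n)
    if (gender_offset_sd != 0 && nm[j] %in% shift_scales)
      mu[female] <- mu[female] + gender_offset_sd * sp$sd
    uj <- u[, j]
    if (sp$zero_inflation > 0) {
      x <- numeric(n)
      nz <- uj > sp$zero_inflation
      v <- (uj[nz] - sp$zero_inflation) / (1 - sp$zero_inflation)
      x[nz] <- .qtruncnorm(v, mu[nz], par$sigma, sp$min, sp$max)
    } else {
      x <- .qtruncnorm(uj, mu, par$sigma, sp$min, sp$max)
    }
    out[, j] <- x
  }
  out
}

#' Generate a synthetic cohort of contrast maps and subject records
#'
#' Forward model, per subject: `volume = z * a * W + scanner_offset[B] +
#' noise`, where `z` is the cohort-standardized primary score, `W` the
#' ground-truth pattern (random signs at the signal voxels, zero elsewhere),
#' `a = signal_snr * noise_sd` so the per-signal-voxel SNR equals
#' `signal_snr`, `scanner_offset` an additive per-voxel map applied to
#' scanner-B subjects, and `noise` i.i.d. Gaussian. A `dropout_fraction` of
#' subjects receives a contiguous NaN patch covering `dropout_extent` of all
#' voxels in the fixed frontal octant. Signal voxels are drawn outside that
#' octant so they survive common-voxel masking. Deterministic given
#' `config$seed` (the caller's RNG state is left untouched).
#'
#' @param config A [cohort_config()].
#' @param scale_specs Per-scale, per-group specs as from
#'   [default_scale_specs()].
#' @return List with `records` (list of subject records: `subject_id`,
#'   `volume`, `scores`, `age`, `gender`, `scanner`, `group`), `truth` (list:
#'   `true_weight_volume`, `signal_voxel_indices`, `scanner_offset_volume`)
#'   and `config`.
#' @export
generate_cohort <- function(config, scale_specs = default_scale_specs()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!config$primary_scale %in% names(scale_specs))
    stop("primary_scale not among the scale specs")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  gs <- config$grid_shape
  n_vox <- prod(gs)
  n_d <- config$n_distressed; n_h <- config$n_healthy
  n <- n_d + n_h
  groups <- c(rep("distressed", n_d), rep("healthy", n_h))

  # demographics ----------------------------------------------------------
  female <- stats::runif(n) < config$female_fraction
  gender <- ifelse(female, "F", "M")
  age <- .rtruncnorm(n, config$age_mean, config$age_sd,
                     config$age_range[1], config$age_range[2])
  scanner <- character(n)
  for (grp in c("distressed", "healthy")) {
    idx <- which(groups == grp)
    sp <- config$scanner_split[[grp]]
    lab <- c(rep("A", sp[["A"]]), rep("B", sp[["B"]]))
    scanner[idx] <- sample(lab)
  }

  # scores ----------------------------------------------------------------
  scores <- matrix(NA_real_, n, length(scale_specs),
                   dimnames = list(NULL, names(scale_specs)))
  for (grp in c("distressed", "healthy")) {
    idx <- which(groups == grp)
    scores[idx, ] <- .draw_group_scores(scale_specs, grp, length(idx),
                                        config$score_correlation, female[idx],
                                        config$gender_offset_sd)
  }

  # ground-truth pattern ---------------------------------------------------
  octant <- .frontal_octant_indices(gs)
  if (is.null(config$signal_voxels)) {
    candidates <- setdiff(seq_len(n_vox), octant)
    if (config$n_signal_voxels > length(candidates))
      stop("n_signal_voxels exceeds voxels outside the dropout octant")
    sig_idx <- sort(sample(candidates, config$n_signal_voxels))
  } else {
    sig_idx <- sort(config$signal_voxels)
  }
  W <- array(0, gs)
  W[sig_idx] <- sample(c(-1, 1), length(sig_idx), replace = TRUE)
  amplitude <- config$signal_snr * config$noise_sd
  scanner_offset <- array(stats::rnorm(n_vox, 0, config$scanner_offset_sd), gs)
  if (config$scanner_offset_sd == 0) scanner_offset <- array(0, gs)

  z <- as.numeric(scale(scores[, config$primary_scale]))

  # dropout patch: contiguous raster-order prefix of the frontal octant ----
  k_drop <- as.integer(round(config$dropout_extent * n_vox))
  n_drop <- as.integer(round(config$dropout_fraction * n))
  drop_subjects <- if (n_drop > 0) sort(sample(n, n_drop)) else integer(0)
  patch <- if (k_drop > 0) octant[seq_len(k_drop)] else integer(0)

  # volumes ----------------------------------------------------------------
  records <- vector("list", n)
  ids <- sprintf("sub-%03d", seq_len(n))
  for (i in seq_len(n)) {
    vol <- array(stats::rnorm(n_vox, 0, config$noise_sd), gs)
    if (amplitude > 0) vol <- vol + z[i] * amplitude * W
    if (scanner[i] == "B") vol <- vol + scanner_offset
    if (i %in% drop_subjects && k_drop > 0) vol[patch] <- NaN
    records[[i]] <- list(subject_id = ids[i], volume = vol,
                         scores = scores[i, ], age = age[i],
                         gender = gender[i], scanner = scanner[i],
                         group = groups[i])
  }
  truth <- list(true_weight_volume = W, signal_voxel_indices = sig_idx,
                scanner_offset_volume = scanner_offset,
                dropout_subjects = ids[drop_subjects],
                dropout_voxel_indices = patch)
  list(records = records, truth = truth, config = config)
}

#' Subject table from cohort records
#'
#' @param records List of subject records as produced by [generate_cohort()].
#' @return `data.frame` with columns `subject_id`, `group`, `scanner`,
#'   `gender`, `age`, `stai_t`, `stai_s`, `masq_d`, `ham_a`, `hdrs`.
#' @export
subject_table <- function(records) {
  score_cols <- c(stai_t = "STAI-T", stai_s = "STAI-S", masq_d = "MASQ-D",
                  ham_a = "HAM-A", hdrs = "HDRS")
  df <- data.frame(
    subject_id = vapply(records, `[[`, "", "subject_id"),
    group = vapply(records, `[[`, "", "group"),
    scanner = vapply(records, `[[`, "", "scanner"),
    gender = vapply(records, `[[`, "", "gender"),
    age = vapply(records, `[[`, 0, "age"),
    stringsAsFactors = FALSE)
  for (col in names(score_cols))
    df[[col]] <- vapply(records, function(r) unname(r$scores[[score_cols[[col]]]]), 0)
  df
}

#' Map CSV column names to scale names
#'
#' @param scale Scale name such as `"STAI-T"`.
#' @return The subject-table column name, e.g. `"stai_t"`.
#' @export
scale_column <- function(scale) {
  map <- c("STAI-T" = "stai_t", "STAI-S" = "stai_s", "MASQ-D" = "masq_d",
           "HAM-A" = "ham_a", "HDRS" = "hdrs")
  if (!scale %in% names(map)) stop("unknown scale: ", scale)
  unname(map[[scale]])
}

#' Write a cohort to disk
#'
#' Writes one NIfTI volume per subject, the subject table CSV, the
#' ground-truth weight volume, and a JSON manifest with per-file MD5 hashes
#' (no timestamps, so identical cohorts produce identical manifests).
#'
#' @param records,ground_truth As returned by [generate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_cohort <- function(records, ground_truth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (r in records) {
    f <- file.path(out_dir, paste0(r$subject_id, ".nii.gz"))
    nifti_write(r$volume, f, datatype = "float32",
                descrip = paste0("contrast ", r$subject_id))
    files <- c(files, f)
  }
  csv <- file.path(out_dir, "cohort.csv")
  utils::write.csv(subject_table(records), csv, row.names = FALSE)
  truth_f <- file.path(out_dir, "truth.nii.gz")
  nifti_write(ground_truth$true_weight_volume, truth_f,
              datatype = "float64", descrip = "true weight volume")
  all_files <- c(files, csv, truth_f)
  manifest <- list(
    n_subjects = length(records),
    files = lapply(all_files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))),
    signal_voxel_indices = ground_truth$signal_voxel_indices,
    dropout_subjects = ground_truth$dropout_subjects)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate a labelled atlas volume
#'
#' Partitions the grid into `n_regions` contiguous blocks. When `n_regions`
#' factors into three integers no larger than the grid dimensions, the grid
#' is cut into a box lattice (e.g. 8 regions on a cube gives the octants);
#' otherwise voxels are cut into `n_regions` near-equal contiguous runs in
#' raster order. Every voxel receives exactly one label in `1..n_regions`.
#'
#' @param grid_shape Integer length-3 grid.
#' @param n_regions Number of regions, `<= prod(grid_shape)`.
#' @return Integer 3-D array of region labels.
#' @export
generate_atlas <- function(grid_shape, n_regions) {
  grid_shape <- as.integer(grid_shape)
  n_vox <- prod(grid_shape)
  n_regions <- as.integer(n_regions)
  if (n_regions < 1 || n_regions > n_vox)
    stop("n_regions must be in 1..", n_vox)

  # best factorization n_regions = f1*f2*f3 with fi <= dim_i
  best <- NULL
  for (f1 in seq_len(min(n_regions, grid_shape[1]))) {
    if (n_regions %% f1 != 0) next
    r1 <- n_regions %/% f1
    for (f2 in seq_len(min(r1, grid_shape[2]))) {
      if (r1 %% f2 != 0) next
      f3 <- r1 %/% f2
      if (f3 > grid_shape[3]) next
      spread <- max(f1, f2, f3) - min(f1, f2, f3)
      if (is.null(best) || spread < best$spread)
        best <- list(f = c(f1, f2, f3), spread = spread)
    }
  }
  atlas <- array(0L, grid_shape)
  if (!is.null(best)) {
    cuts <- lapply(1:3, function(ax) {
      # near-equal integer partition of the axis into best$f[ax] intervals
      sizes <- diff(round(seq(0, grid_shape[ax], length.out = best$f[ax] + 1)))
      rep(seq_len(best$f[ax]), times = sizes)
    })
    lab_grid <- array(0L, best$f)
    lab_grid[] <- seq_len(n_regions)
    for (i in seq_len(grid_shape[1]))
      for (j in seq_len(grid_shape[2]))
        atlas[i, j, ] <- lab_grid[cuts[[1]][i], cuts[[2]][j], cuts[[3]]]
  } else {
    sizes <- diff(round(seq(0, n_vox, length.out = n_regions + 1)))
    atlas[] <- rep(seq_len(n_regions), times = sizes)
  }
  atlas
}
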
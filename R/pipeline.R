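# Pipeline orchestration: simulate -> QC/mask -> decode -> permute ->
# localize -> report, behind a JSON config and a small CLI (inst/cli).
#
# Every stage is a plain function over a validated config list, so the CLI
# is a thin wrapper and the full analysis is reproducible from R with
# run_config() + the cmd_* functions.

.default_config <- function() {
  list(
    paths = list(cohort_dir = "cohort", atlas = NULL, out_dir = "results"),
    cohort = list(),                    # overrides for cohort_config()
    n_regions = 27L,
    scales = c("STAI-T", "STAI-S", "MASQ-D", "HAM-A", "HDRS"),
    cv_k = c(2L, 5L),
    scopes = "whole",
    confounds = "age",
    confounds_distressed = c("age", "scanner"),
    balance_keys = "scanner",
    fold_alpha = 0.05,
    max_nan_fraction = 0.15,
    n_permutations = 1000L,
    nw_mode = "literal",
    localize = list(scale = "STAI-T", k = 2L, top_k = 20L),
    seeds = list(cohort = 1L, folds = 2L, permutations = 3L)
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load and validate a run configuration
#'
#' @param config Path to a JSON config file, or a named list of overrides;
#'   `NULL` gives the package defaults. Unknown scale names, CV schemes
#'   outside `{2, 5}`, or scopes outside `{whole, distressed, healthy}` are
#'   rejected.
#' @return A validated `run_config` list, with `config_hash` (MD5 of the
#'   canonical JSON) attached.
#' @export
run_config <- function(config = NULL) {
  override <- if (is.null(config)) list()
    else if (is.character(config)) jsonlite::read_json(config, simplifyVector = TRUE)
    else config
  cfg <- .merge_config(.default_config(), override)
  known <- c("STAI-T", "STAI-S", "MASQ-D", "HAM-A", "HDRS")
  if (!all(cfg$scales %in% known))
    stop("unknown scale(s): ", paste(setdiff(cfg$scales, known), collapse = ", "))
  cfg$cv_k <- as.integer(cfg$cv_k)
  if (!all(cfg$cv_k %in% c(2L, 5L)))
    stop("cv_k must be a subset of {2, 5}")
  if (!all(cfg$scopes %in% c("whole", "distressed", "healthy")))
    stop("scopes must be a subset of {whole, distressed, healthy}")
  if (!cfg$nw_mode %in% c("literal", "mean")) stop("nw_mode must be literal|mean")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  cfg$config_hash <- unname(tools::md5sum(tmp))
  class(cfg) <- c("run_config", "list")
  cfg
}

.provenance <- function(cfg) {
  list(config_hash = cfg$config_hash, seeds = cfg$seeds,
       package = "gpdecode",
       version = as.character(utils::packageVersion("gpdecode")))
}

# Deterministic per-cell seed derivation (kept < 2^31).
.cell_seed <- function(base, scope, scale, k) {
  scopes <- c(whole = 0L, distressed = 1L, healthy = 2L)
  scales <- c("STAI-T" = 1L, "STAI-S" = 2L, "MASQ-D" = 3L, "HAM-A" = 4L,
              "HDRS" = 5L, "group" = 6L)
  (as.integer(base) + 7919L * scopes[[scope]] + 1009L * scales[[scale]] +
     101L * as.integer(k)) %% 2147483647L
}

#' Simulate a cohort and atlas to disk
#'
#' Generates the synthetic cohort configured under `config$cohort` (see
#' [cohort_config()]; `seed` defaults to `config$seeds$cohort`), writes the
#' per-subject NIfTI volumes, subject CSV, ground truth and manifest to
#' `config$paths$cohort_dir`, plus an integer atlas (`atlas.nii.gz`) with
#' `config$n_regions` regions.
#'
#' @param config See [run_config()].
#' @return Invisibly, the cohort manifest.
#' @export
cmd_simulate <- function(config = NULL) {
  cfg <- run_config(config)
  cc_args <- cfg$cohort
  if (is.null(cc_args$seed)) cc_args$seed <- cfg$seeds$cohort
  cc <- do.call(cohort_config, cc_args)
  message("simulate: generating cohort (n=", cc$n_distressed + cc$n_healthy,
          ", grid ", paste(cc$grid_shape, collapse = "x"),
          ", seed ", cc$seed, ")")
  co <- generate_cohort(cc)
  manifest <- write_cohort(co$records, co$truth, cfg$paths$cohort_dir)
  atlas <- generate_atlas(cc$grid_shape, cfg$n_regions)
  nifti_write(atlas, file.path(cfg$paths$cohort_dir, "atlas.nii.gz"),
              datatype = "int32", descrip = "synthetic atlas")
  message("simulate: wrote ", manifest$n_subjects, " volumes + atlas to ",
          cfg$paths$cohort_dir)
  invisible(manifest)
}

#' Load a cohort directory written by [cmd_simulate()]/[write_cohort()]
#'
#' @param cohort_dir Directory with `cohort.csv` and per-subject NIfTI files.
#' @return List with `volumes` (named list of 3-D arrays) and `table`.
#' @export
load_cohort <- function(cohort_dir) {
  csv <- file.path(cohort_dir, "cohort.csv")
  if (!file.exists(csv)) stop("no cohort.csv in ", cohort_dir)
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  vols <- lapply(tab$subject_id, function(id)
    nifti_read(file.path(cohort_dir, paste0(id, ".nii.gz"))))
  names(vols) <- tab$subject_id
  list(volumes = vols, table = tab)
}

# Shared QC + masking + feature assembly for one cohort scope.
.prepare_scope <- function(volumes, tab, cfg, scope) {
  idx <- if (scope == "whole") seq_len(nrow(tab)) else which(tab$group == scope)
  if (!length(idx)) stop("scope '", scope, "' matches no subjects")
  vols <- volumes[idx]; stab <- tab[idx, , drop = FALSE]
  scope_mask <- default_scope_mask(vols)
  excl <- exclude_subjects(vols, scope_mask, cfg$max_nan_fraction,
                           ids = stab$subject_id)
  keep <- excl$report$kept
  vols <- vols[keep]; stab <- stab[keep, , drop = FALSE]
  mask <- build_common_mask(vols, scope_mask)
  feats <- assemble_features(vols, mask, ids = stab$subject_id)
  confounds <- if (scope == "distressed") cfg$confounds_distressed else cfg$confounds
  list(features = feats, table = stab, mask = mask, exclusion = excl,
       confounds = confounds, scope = scope)
}

#' Decode clinical scores from contrast maps
#'
#' For every requested cohort scope, scale and CV scheme: subject exclusion,
#' common-voxel masking, scanner-balanced folds, cross-validated GPR with
#' train/test-separated confound removal, Pearson r and normalized MSE, and
#' a permutation test. Significance flags compare `p_r` and `p_mse`
#' independently against the Bonferroni threshold
#' `0.05 / (n_scales * n_schemes)`. A failure in one scale-scheme cell is
#' recorded in that cell and does not abort the others.
#'
#' Artifacts written to `config$paths$out_dir`: `report.json`,
#' `metrics.csv`, `scatter.csv`, `folds.csv`, `exclusions.csv`, per-scope
#' `mask_<scope>.nii.gz` (0/1) and `screening_<scope>.csv`
#' (confound-association report), and one weight-map NIfTI per decoded cell
#' (`weights_<scope>_<scale>_k<k>.nii.gz`, unit Euclidean norm over masked
#' voxels, zero elsewhere).
#'
#' @param config See [run_config()].
#' @return Invisibly, the report list.
#' @export
cmd_decode <- function(config = NULL) {
  cfg <- run_config(config)
  out <- cfg$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  co <- load_cohort(cfg$paths$cohort_dir)
  thr <- bonferroni_threshold(length(cfg$scales), length(cfg$cv_k))

  results <- list(); scatter <- list(); folds_out <- list(); excl_out <- list()
  for (scope in cfg$scopes) {
    prep <- tryCatch(.prepare_scope(co$volumes, co$table, cfg, scope),
                     error = function(e) e)
    if (inherits(prep, "error")) {
      results[[length(results) + 1L]] <-
        list(scope = scope, error = conditionMessage(prep))
      next
    }
    excl_out[[scope]] <- cbind(scope = scope, prep$exclusion$report)
    nifti_write(array(as.integer(prep$mask$array), dim(prep$mask$array)),
                file.path(out, sprintf("mask_%s.nii.gz", scope)),
                datatype = "uint8", descrip = paste("common mask", scope))
    screen <- tryCatch(
      screen_confounds(prep$table,
                       scales = vapply(cfg$scales, scale_column, ""),
                       confounds = intersect(c("scanner", "gender", "age"),
                                             names(prep$table))),
      error = function(e) NULL)
    if (!is.null(screen))
      utils::write.csv(cbind(scope = scope, screen),
                       file.path(out, sprintf("screening_%s.csv", scope)),
                       row.names = FALSE)
    y_all <- prep$table
    for (scale in cfg$scales) {
      y <- y_all[[scale_column(scale)]]
      for (k in cfg$cv_k) {
        cell <- sprintf("%s/%s/k=%d", scope, scale, k)
        res <- tryCatch({
          fseed <- .cell_seed(cfg$seeds$folds, scope, scale, k)
          folds <- make_balanced_folds(prep$table, k,
                                       target = scale_column(scale),
                                       balance_keys = cfg$balance_keys,
                                       alpha = cfg$fold_alpha, seed = fseed)
          closure <- cv_gpr_closure(prep$features, prep$table, folds,
                                    confounds = prep$confounds)
          obs <- closure(y)
          pt <- permutation_test(closure, y,
                                 n_permutations = cfg$n_permutations,
                                 seed = .cell_seed(cfg$seeds$permutations,
                                                   scope, scale, k),
                                 observed = obs)
          fit <- run_cv(prep$features, y, prep$table, folds,
                        confounds = prep$confounds, model_spec = "gpr")
          wmap <- average_weight_maps(lapply(fit$fold_models, `[[`, "weights"))
          wfile <- file.path(out, sprintf("weights_%s_%s_k%d.nii.gz",
                                          scope, gsub("-", "", scale), k))
          nifti_write(vector_to_volume(wmap$weights, prep$mask), wfile,
                      datatype = "float64",
                      descrip = sprintf("GPR weights %s", cell))
          folds_out[[cell]] <- data.frame(
            scope = scope, scale = scale, k = k,
            subject_id = prep$table$subject_id, fold = folds$fold)
          scatter[[cell]] <- data.frame(
            scope = scope, scale = scale, k = k,
            subject_id = prep$table$subject_id,
            predicted = obs$predicted, actual = y,
            group = prep$table$group, fold = folds$fold)
          message(sprintf("decode %-28s r=%+.3f nMSE=%.3f p_r=%.4g p_mse=%.4g",
                          cell, obs$r, obs$nmse, pt$p_r, pt$p_mse))
          list(scope = scope, scale = scale, k = k, n = length(y),
               r = obs$r, nmse = obs$nmse,
               p_r = pt$p_r, p_mse = pt$p_mse,
               p_r_conservative = pt$p_r_conservative,
               p_mse_conservative = pt$p_mse_conservative,
               n_permutations = pt$n_permutations,
               significant_r = pt$p_r < thr, significant_mse = pt$p_mse < thr,
               weight_file = basename(wfile), fold_tries = folds$tries)
        }, error = function(e) list(scope = scope, scale = scale, k = k,
                                    error = conditionMessage(e)))
        if (!is.null(res$error))
          message("decode ", cell, " FAILED: ", res$error)
        results[[length(results) + 1L]] <- res
      }
    }
  }
  report <- list(provenance = .provenance(cfg),
                 bonferroni_threshold = thr,
                 results = lapply(results, function(r)
                   lapply(r, function(v) if (is.numeric(v)) signif(v, 12) else v)))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  ok <- Filter(function(r) is.null(r$error), results)
  if (length(ok)) {
    metrics <- do.call(rbind, lapply(ok, function(r)
      data.frame(scope = r$scope, scale = r$scale, k = r$k, n = r$n,
                 r = r$r, nmse = r$nmse, p_r = r$p_r, p_mse = r$p_mse,
                 significant_r = r$significant_r,
                 significant_mse = r$significant_mse)))
    utils::write.csv(metrics, file.path(out, "metrics.csv"), row.names = FALSE)
  }
  if (length(scatter))
    utils::write.csv(do.call(rbind, scatter), file.path(out, "scatter.csv"),
                     row.names = FALSE)
  if (length(folds_out))
    utils::write.csv(do.call(rbind, folds_out), file.path(out, "folds.csv"),
                     row.names = FALSE)
  if (length(excl_out))
    utils::write.csv(do.call(rbind, excl_out), file.path(out, "exclusions.csv"),
                     row.names = FALSE)
  invisible(report)
}

#' Classify distressed versus healthy subjects
#'
#' Gaussian-process classification with the same masking, confound and fold
#' machinery as [cmd_decode()] (folds additionally stratified by group so
#' both classes appear in every training fold). Reports balanced accuracy,
#' per-class accuracies, and a label-permutation p-value per CV scheme.
#' Appends a `classification` block to `report.json` when present, else
#' writes `classification.json`.
#'
#' @param config See [run_config()].
#' @return Invisibly, the classification block (list per CV scheme).
#' @export
cmd_classify <- function(config = NULL) {
  cfg <- run_config(config)
  out <- cfg$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  co <- load_cohort(cfg$paths$cohort_dir)
  if (length(unique(co$table$group)) < 2)
    stop("classification needs both groups in the cohort")
  prep <- .prepare_scope(co$volumes, co$table, cfg, "whole")
  labels <- prep$table$group

  blocks <- list()
  for (k in cfg$cv_k) {
    res <- tryCatch({
      fseed <- .cell_seed(cfg$seeds$folds, "whole", "group", k)
      folds <- make_balanced_folds(prep$table, k, target = NULL,
                                   balance_keys = unique(c(cfg$balance_keys, "group")),
                                   alpha = cfg$fold_alpha, seed = fseed)
      closure <- cv_gpc_closure(prep$features, prep$table, folds,
                                confounds = prep$confounds)
      obs <- closure(labels)
      pt <- permutation_test_classification(
        closure, labels, n_permutations = cfg$n_permutations,
        seed = .cell_seed(cfg$seeds$permutations, "whole", "group", k),
        observed = obs)
      message(sprintf("classify k=%d balanced=%.3f (%s) p=%.4g", k,
                      obs$balanced,
                      paste(sprintf("%s=%.3f", names(obs$per_class),
                                    obs$per_class), collapse = ", "),
                      pt$p_balanced))
      list(k = k, n = length(labels),
           balanced_accuracy = obs$balanced,
           per_class = as.list(obs$per_class),
           p_balanced = pt$p_balanced,
           p_balanced_conservative = pt$p_balanced_conservative,
           n_permutations = pt$n_permutations)
    }, error = function(e) list(k = k, error = conditionMessage(e)))
    blocks[[length(blocks) + 1L]] <- res
  }
  rep_file <- file.path(out, "report.json")
  if (file.exists(rep_file)) {
    report <- jsonlite::read_json(rep_file)
    report$classification <- blocks
    jsonlite::write_json(report, rep_file, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    jsonlite::write_json(list(provenance = .provenance(cfg),
                              classification = blocks),
                         file.path(out, "classification.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(blocks)
}

#' Cross-validated GPC closure (label-permutation machinery)
#'
#' Classification analogue of [cv_gpr_closure()]: per-fold residualized
#' kernels are precomputed once; the returned closure fits the GP classifier
#' for an arbitrary label vector and returns balanced accuracy.
#'
#' @inheritParams cv_gpr_closure
#' @return Function `f(labels)` returning `balanced`, `per_class`,
#'   `probabilities`, `predicted_labels`.
#' @export
cv_gpc_closure <- function(features, table = NULL, folds,
                           confounds = character(0)) {
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
    list(tr = tr, te = te, K = linear_kernel(Xtr),
         K_te_tr = linear_kernel(Xte, Xtr), k_te_diag = rowSums(Xte^2))
  })
  function(labels) {
    labels <- as.character(labels)
    stopifnot(length(labels) == n)
    lev <- sort(unique(labels))
    if (length(lev) != 2) stop("need exactly 2 classes")
    prob <- rep(NA_real_, n)
    for (p in pre) {
      m <- fit_gpc(p$K, labels[p$tr])
      prob[p$te] <- predict_gpc(m, p$K_te_tr, p$k_te_diag)
    }
    pred <- ifelse(prob > 0.5, lev[2], lev[1])
    ba <- balanced_accuracy(labels, pred)
    list(balanced = ba$balanced, per_class = ba$per_class,
         probabilities = prob, predicted_labels = pred)
  }
}

#' Localize a decoded weight map over atlas regions
#'
#' Reads the weight map written by [cmd_decode()] for the configured
#' `localize` cell, summarizes it over the atlas with
#' [region_normalized_weights()] in the configured NW mode, and writes
#' `regions.csv` (rank, region, n_voxels, NW, pct_NW, mode).
#'
#' @param config See [run_config()].
#' @return Invisibly, the `region_weight_table` with the top-k summary as
#'   attribute `top_k`.
#' @export
cmd_localize <- function(config = NULL) {
  cfg <- run_config(config)
  out <- cfg$paths$out_dir
  scale <- cfg$localize$scale; k <- cfg$localize$k
  wfile <- file.path(out, sprintf("weights_whole_%s_k%d.nii.gz",
                                  gsub("-", "", scale), k))
  if (!file.exists(wfile)) stop("missing weight map ", wfile,
                                " - run cmd_decode first")
  atlas_file <- if (!is.null(cfg$paths$atlas)) cfg$paths$atlas
                else file.path(cfg$paths$cohort_dir, "atlas.nii.gz")
  if (!file.exists(atlas_file)) stop("missing atlas ", atlas_file)
  atlas <- nifti_read(atlas_file)
  wvol <- nifti_read(wfile)
  mask <- brain_mask(wvol != 0)
  tab <- region_normalized_weights(wvol[mask$indices], atlas, mask,
                                   mode = cfg$nw_mode)
  top <- top_k_summary(tab, min(cfg$localize$top_k, nrow(tab)))
  utils::write.csv(as.data.frame(tab), file.path(out, "regions.csv"),
                   row.names = FALSE)
  message(sprintf("localize: top %d regions carry %.1f%% of total NW (%s mode)",
                  nrow(top$top), top$cumulative_pct_NW, cfg$nw_mode))
  attr(tab, "top_k") <- top
  invisible(tab)
}

#' Summarize a completed run
#'
#' Reads the artifacts in `config$paths$out_dir` and prints a metrics grid
#' (scales x CV schemes), the classification block if present, and the
#' top-k region table if present. Returns the assembled summary.
#'
#' @param config See [run_config()].
#' @return List with `metrics`, `classification`, `regions`, `provenance`.
#' @export
cmd_report <- function(config = NULL) {
  cfg <- run_config(config)
  out <- cfg$paths$out_dir
  rep_file <- file.path(out, "report.json")
  if (!file.exists(rep_file)) stop("missing ", rep_file, " - run cmd_decode")
  report <- jsonlite::read_json(rep_file, simplifyVector = TRUE)
  metrics_file <- file.path(out, "metrics.csv")
  metrics <- if (file.exists(metrics_file))
    utils::read.csv(metrics_file, stringsAsFactors = FALSE) else NULL
  regions_file <- file.path(out, "regions.csv")
  regions <- if (file.exists(regions_file))
    utils::read.csv(regions_file, stringsAsFactors = FALSE) else NULL
  if (!is.null(metrics)) {
    cat("Agreement between actual and decoded scores",
        sprintf("(Bonferroni threshold %.4g)\n", report$bonferroni_threshold))
    print(metrics, row.names = FALSE, digits = 3)
  }
  if (!is.null(report$classification)) {
    cat("\nDistressed-vs-healthy classification\n")
    cls <- report$classification
    if (is.data.frame(cls)) print(cls, row.names = FALSE, digits = 3)
    else for (b in cls) if (is.null(b$error))
      cat(sprintf("  k=%d balanced=%.3f p=%.4g\n",
                  b$k, b$balanced_accuracy, b$p_balanced))
  }
  if (!is.null(regions)) {
    cat("\nTop regions by normalized weight\n")
    print(utils::head(regions, 20), row.names = FALSE, digits = 3)
  }
  cat("\nProvenance: config", report$provenance$config_hash, "\n")
  invisible(list(metrics = metrics, classification = report$classification,
                 regions = regions, provenance = report$provenance))
}
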
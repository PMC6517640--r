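# Weight-map aggregation and atlas-based pattern localization.
#
# Two normalized-weight (NW) conventions are implemented. The "literal" mode
# divides the regional mean absolute weight by the region's voxel count a
# second time (NW = mean(|w|)/n_region) — a double size-normalization; the
# "mean" mode is the conventional size-normalized sum, i.e. the plain
# regional mean(|w|). The modes coincide (up to ranking) only when all
# regions have equal size. The literal formula is the package default and
# every output names the mode used.

#' Average per-fold weight vectors into a unit-norm weight map
#'
#' Element-wise mean across folds (per-fold vectors enter un-normalized),
#' then division of the mean vector by its Euclidean norm.
#'
#' @param fold_weights List of equal-length numeric vectors (or a matrix
#'   with one column per fold).
#' @return A `weight_map`: `weights` (unit Euclidean norm), `n_folds`,
#'   `euclidean_norm_applied = TRUE`.
#' @export
average_weight_maps <- function(fold_weights) {
  W <- if (is.matrix(fold_weights)) fold_weights
       else do.call(cbind, lapply(fold_weights, as.numeric))
  if (is.null(W) || ncol(W) < 1) stop("need at least one fold weight vector")
  m <- rowMeans(W)
  nrm <- sqrt(sum(m^2))
  if (nrm == 0) stop("zero-norm mean weight vector: folds cancel exactly")
  structure(list(weights = m / nrm, n_folds = ncol(W),
                 euclidean_norm_applied = TRUE),
            class = "weight_map")
}

#' Summarize a weight map over atlas regions as normalized weights
#'
#' For each region `R` of the atlas (restricted to the mask),
#' `NW_R = mean(|w_v| : v in R) / |R|` in `"literal"` mode, or
#' `NW_R = mean(|w_v| : v in R)` in `"mean"` mode. Regions are then ranked
#' by their percentage of the total NW (`%NW = 100 NW / sum(NW)`),
#' descending, ties broken by label order. Label 0 marks unlabelled voxels:
#' they are excluded from the table and their total absolute weight is
#' reported separately. Labelled regions with no masked voxels are dropped
#' with a warning.
#'
#' @param map A [average_weight_maps()] result (or plain numeric vector
#'   aligned to the mask ordering).
#' @param atlas Integer 3-D label volume on the mask's grid.
#' @param mask A [brain_mask()] giving the voxel ordering of the weights.
#' @param mode `"literal"` (default) or `"mean"`.
#' @param region_names Optional named map label -> region name.
#' @return A `region_weight_table`: `data.frame` (`rank`, `region`, `label`,
#'   `n_voxels`, `NW`, `pct_NW`, `mode`) with attribute
#'   `unlabelled_abs_weight`.
#' @export
region_normalized_weights <- function(map, atlas, mask,
                                      mode = c("literal", "mean"),
                                      region_names = NULL) {
  mode <- match.arg(mode)
  w <- if (inherits(map, "weight_map")) map$weights else as.numeric(map)
  stopifnot(inherits(mask, "brain_mask"), length(w) == mask$voxel_count)
  if (!identical(dim(atlas), dim(mask$array)))
    stop("atlas grid does not match mask grid")
  lab <- as.integer(atlas[mask$indices])
  if (anyNA(lab) || any(lab < 0)) stop("atlas labels must be integers >= 0")

  unlab <- sum(abs(w[lab == 0L]))
  keep <- lab > 0L
  labs <- sort(unique(lab[keep]))
  all_labs <- sort(setdiff(unique(as.integer(atlas)), 0L))
  empty <- setdiff(all_labs, labs)
  if (length(empty))
    warning("dropping ", length(empty),
            " region(s) with no masked voxels: ",
            paste(utils::head(empty, 10), collapse = ", "))

  n_vox <- vapply(labs, function(l) sum(lab == l), 0L)
  mean_abs <- vapply(labs, function(l) mean(abs(w[lab == l])), 0)
  NW <- if (mode == "literal") mean_abs / n_vox else mean_abs
  pct <- 100 * NW / sum(NW)
  ord <- order(-pct, labs)
  nm <- if (is.null(region_names)) sprintf("region_%03d", labs)
        else {
          got <- region_names[as.character(labs)]
          ifelse(is.na(got), sprintf("region_%03d", labs), got)
        }
  tab <- data.frame(rank = seq_along(ord), region = nm[ord],
                    label = labs[ord], n_voxels = n_vox[ord], NW = NW[ord],
                    pct_NW = pct[ord], mode = mode,
                    stringsAsFactors = FALSE)
  attr(tab, "unlabelled_abs_weight") <- unlab
  class(tab) <- c("region_weight_table", "data.frame")
  tab
}

#' Top-k region summary
#'
#' @param table A [region_normalized_weights()] result.
#' @param k Number of top-ranked regions, `1 <= k <= nrow(table)`.
#' @return List with `top` (the first `k` rows by rank) and
#'   `cumulative_pct_NW` (sum of their `%NW`).
#' @export
top_k_summary <- function(table, k) {
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(table)) stop("k exceeds the number of regions")
  top <- table[order(table$rank)[seq_len(k)], , drop = FALSE]
  list(top = top, cumulative_pct_NW = sum(top$pct_NW))
}
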
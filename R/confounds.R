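# Confound screening and train/test-separated confound removal.
#
# Confounds are removed from the *features*, never from the targets:
# residualizing targets on confounds associated with the predicted variable
# removes label-related variability along with the nuisance. Removal
# parameters (regression coefficients and the z-scoring statistics of
# continuous confounds) are estimated on training rows only and applied
# unchanged to test rows, so no test-fold information leaks into training.

#' Screen confound-score associations
#'
#' For each binary confound (e.g. scanner, gender) and each scale, a Welch
#' two-sample t-test; for each continuous confound (e.g. age), a Pearson
#' correlation test. No multiplicity correction — this is a screening step
#' that informs which confounds to remove, not an inference.
#'
#' @param table Subject `data.frame` (see [subject_table()]).
#' @param scales Character vector of score column names to screen.
#' @param confounds Character vector of confound column names.
#' @return `data.frame` with columns `confound`, `scale`, `test`,
#'   `statistic`, `p_value`.
#' @export
screen_confounds <- function(table, scales, confounds) {
  if (nrow(table) < 3) stop("need at least 3 subjects")
  rows <- list()
  for (cf in confounds) {
    x <- table[[cf]]
    if (is.null(x)) stop("confound column not found: ", cf)
    categorical <- is.character(x) || is.factor(x) || is.logical(x)
    if (categorical) {
      lev <- unique(as.character(x))
      if (length(lev) != 2)
        stop("categorical confound '", cf, "' must have exactly 2 levels, has ",
             length(lev))
    }
    for (sc in scales) {
      y <- table[[sc]]
      if (is.null(y)) stop("scale column not found: ", sc)
      if (stats::sd(y) == 0) stop("scale '", sc, "' is constant")
      if (categorical) {
        g1 <- y[as.character(x) == lev[1]]
        g2 <- y[as.character(x) == lev[2]]
        if (stats::sd(g1) == 0 && stats::sd(g2) == 0 && mean(g1) == mean(g2)) {
          stat <- 0; p <- 1   # identical degenerate groups: no association
        } else {
          tt <- stats::t.test(g1, g2)
          stat <- unname(tt$statistic); p <- tt$p.value
        }
        rows[[length(rows) + 1L]] <-
          data.frame(confound = cf, scale = sc, test = "two-sample t",
                     statistic = stat, p_value = p)
      } else {
        ct <- stats::cor.test(x, y)
        rows[[length(rows) + 1L]] <-
          data.frame(confound = cf, scale = sc, test = "Pearson",
                     statistic = unname(ct$estimate), p_value = ct$p.value)
      }
    }
  }
  do.call(rbind, rows)
}

# Build the [intercept | confounds] design matrix. Categorical confounds
# become a single 0/1 dummy (binary only); continuous confounds are z-scored
# with the supplied (training) statistics.
.confound_design <- function(table, confounds, standardize = NULL) {
  n <- nrow(table)
  D <- matrix(1, n, 1, dimnames = list(NULL, "(intercept)"))
  std <- if (is.null(standardize)) list() else standardize
  for (cf in confounds) {
    x <- table[[cf]]
    if (is.null(x)) stop("confound column not found: ", cf)
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      x <- as.character(x)
      lev <- if (!is.null(std[[cf]]$levels)) std[[cf]]$levels else sort(unique(x))
      if (length(lev) != 2)
        stop("categorical confound '", cf, "' must be binary")
      bad <- !x %in% lev
      if (any(bad)) stop("unseen level in confound '", cf, "'")
      col <- as.numeric(x == lev[2])
      std[[cf]] <- list(levels = lev)
    } else {
      if (is.null(std[[cf]]$mean)) {
        s <- stats::sd(x)
        std[[cf]] <- list(mean = mean(x), sd = if (s > 0) s else 1)
      }
      col <- (x - std[[cf]]$mean) / std[[cf]]$sd
    }
    D <- cbind(D, col)
    colnames(D)[ncol(D)] <- cf
  }
  list(design = D, standardize = std)
}

#' Fit a confound-removal model on training rows
#'
#' Least-squares regression of every feature column on
#' `[intercept, confounds]` over the training rows only. Continuous
#' confounds are z-scored with training-fold statistics; binary categorical
#' confounds enter as 0/1 dummies. The returned model carries only
#' training-derived state, so applying it to test rows cannot leak.
#'
#' @param X_train Numeric matrix (training subjects x voxels).
#' @param table_train Training-row subject `data.frame`.
#' @param confounds Character vector of confound column names; may be empty
#'   (intercept-only model, i.e. column-mean centring).
#' @return A `confound_model`: list with `coefficients`
#'   ((q+1) x voxels), `confounds`, `standardize`.
#' @export
fit_confound_model <- function(X_train, table_train, confounds = character(0)) {
  X_train <- as.matrix(X_train)
  if (nrow(X_train) != nrow(table_train))
    stop("feature rows and table rows differ")
  cd <- .confound_design(table_train, confounds)
  D <- cd$design
  if (nrow(D) <= ncol(D))
    stop("need more training rows than confound coefficients")
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) stop("rank-deficient confound design")
  B <- qr.coef(qrD, X_train)
  dimnames(B) <- list(colnames(D), NULL)
  structure(list(coefficients = B, confounds = confounds,
                 standardize = cd$standardize),
            class = "confound_model")
}

#' Remove confound effects using a fitted model
#'
#' Subtracts the training-estimated confound fit from the supplied rows:
#' `X - [1, C] B`. On the training rows the residuals are orthogonal to the
#' training design; on test rows they generally are not — that asymmetry is
#' exactly what train/test separation means.
#'
#' @param model A [fit_confound_model()] result.
#' @param X Numeric matrix (subjects x voxels).
#' @param table Subject `data.frame` for the same rows, providing the
#'   confound columns named in the model.
#' @return Residualized matrix, same shape as `X`.
#' @export
remove_confounds <- function(model, X, table) {
  stopifnot(inherits(model, "confound_model"))
  X <- as.matrix(X)
  if (nrow(X) != nrow(table)) stop("feature rows and table rows differ")
  cd <- .confound_design(table, model$confounds, standardize = model$standardize)
  D <- cd$design
  if (!identical(colnames(D), rownames(model$coefficients)))
    stop("confound name/order mismatch between model and data")
  X - D %*% model$coefficients
}
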
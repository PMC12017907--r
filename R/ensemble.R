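#' Construct a feature matrix for ensemble modeling
#'
#' Low-level constructor: takes a numeric predictor table and a response
#' vector over the same cells, z-scores each predictor column (storing the
#' scaling parameters for prediction reuse) and drops zero-variance
#' columns with a warning.
#'
#' @param features numeric matrix or data.frame, cells x predictors.
#' @param response numeric response (standardized bee richness per cell).
#' @param cell_id optional cell identifiers.
#' @param provenance optional named character vector tagging each predictor
#'   `"landcover"` or `"bird"`.
#' @param scale if `FALSE` the columns are used as-is (already scaled).
#' @return an object of class `feature_matrix`: list with `X` (scaled
#'   matrix), `y`, `cell_id`, `center`, `scale`, `provenance`.
#' @export
feature_matrix <- function(features, response, cell_id = NULL,
                           provenance = NULL, scale = TRUE) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  if (length(response) != nrow(X)) stop("response length != feature rows")
  if (anyNA(X) || anyNA(response)) stop("missing values in features/response")
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  names(ctr) <- names(scl) <- colnames(X)
  if (scale) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    zero <- scl == 0 | !is.finite(scl)
    if (any(zero)) {
      warning("dropping zero-variance predictors: ",
              paste(colnames(X)[zero], collapse = ", "))
      X <- X[, !zero, drop = FALSE]
      ctr <- ctr[!zero]; scl <- scl[!zero]
    }
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  if (!is.null(provenance)) provenance <- provenance[colnames(X)]
  structure(list(X = X, y = as.numeric(response),
                 cell_id = cell_id %||% rownames(X) %||%
                   as.character(seq_len(nrow(X))),
                 center = ctr, scale = scl, provenance = provenance),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$X), "cells x", ncol(x$X), "predictors\n")
  if (!is.null(x$provenance)) {
    print(table(x$provenance))
  }
  invisible(x)
}

#' Join richness, land-cover and bird features into a feature matrix
#'
#' Retains only cells present in all supplied inputs (so the three
#' predictor sets are compared on identical cells), restricts the columns
#' to the requested predictor set, and z-scores them.
#'
#' @param cell_richness data.frame `cell_id`, `richness` (the response).
#' @param cell_landcover data.frame `cell_id` + land-cover percentage
#'   columns, or NULL.
#' @param cell_bird_features long data.frame `cell_id`, `species`,
#'   `mean_residual`, or NULL.
#' @param predictor_set which columns enter the matrix.
#' @return a [feature_matrix()] with provenance tags.
#' @export
build_feature_matrix <- function(cell_richness,
                                 cell_landcover = NULL,
                                 cell_bird_features = NULL,
                                 predictor_set = c("birds_and_landcover",
                                                   "landcover_only",
                                                   "birds_only")) {
  predictor_set <- match.arg(predictor_set)
  cells <- cell_richness$cell_id
  lc_mat <- NULL
  if (!is.null(cell_landcover)) {
    lc_cols <- setdiff(names(cell_landcover), c("cell_id", "x", "y"))
    lc_mat <- as.matrix(cell_landcover[, lc_cols, drop = FALSE])
    rownames(lc_mat) <- cell_landcover$cell_id
    cells <- intersect(cells, cell_landcover$cell_id)
  }
  bird_mat <- NULL
  if (!is.null(cell_bird_features)) {
    spp <- sort(unique(cell_bird_features$species))
    bcells <- sort(unique(cell_bird_features$cell_id))
    bird_mat <- matrix(NA_real_, length(bcells), length(spp),
                       dimnames = list(bcells, spp))
    bird_mat[cbind(match(cell_bird_features$cell_id, bcells),
                   match(cell_bird_features$species, spp))] <-
      cell_bird_features$mean_residual
    cells <- intersect(cells, bcells)
  }
  if (length(cells) == 0) stop("no cells shared by all inputs")
  parts <- list(); prov <- character(0)
  if (predictor_set != "birds_only") {
    if (is.null(lc_mat)) stop("predictor set needs land-cover features")
    parts$lc <- lc_mat[cells, , drop = FALSE]
    prov <- c(prov, stats::setNames(rep("landcover", ncol(lc_mat)),
                                    colnames(lc_mat)))
  }
  if (predictor_set != "landcover_only") {
    if (is.null(bird_mat)) stop("predictor set needs bird features")
    parts$bird <- bird_mat[cells, , drop = FALSE]
    prov <- c(prov, stats::setNames(rep("bird", ncol(bird_mat)),
                                    colnames(bird_mat)))
  }
  X <- do.call(cbind, parts)
  if (anyNA(X)) stop("missing feature values after join")
  y <- cell_richness$richness[match(cells, cell_richness$cell_id)]
  fm <- feature_matrix(X, y, cell_id = cells, provenance = prov)
  fm$predictor_set <- predictor_set
  fm
}

## Restrict a feature matrix to named predictors / row indices.
fm_select_predictors <- function(fm, predictors) {
  fm$X <- fm$X[, predictors, drop = FALSE]
  fm$center <- fm$center[predictors]
  fm$scale <- fm$scale[predictors]
  if (!is.null(fm$provenance)) fm$provenance <- fm$provenance[predictors]
  fm
}

fm_subset_rows <- function(fm, idx) {
  fm$X <- fm$X[idx, , drop = FALSE]
  fm$y <- fm$y[idx]
  fm$cell_id <- fm$cell_id[idx]
  fm
}

## Cholesky solve of the normal equations for one subset, guarding against
## (near-)singular subsets — e.g. a full set of compositional land-cover
## percentages, which is exactly collinear.  Returns NULL when the
## relative pivot falls below tol.
chol_solve_subset <- function(C, cxy, S, tol = 1e-8) {
  R <- tryCatch(chol(C[S, S, drop = FALSE]), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  d <- diag(R)
  if (min(d) < tol * max(d)) return(NULL)
  backsolve(R, forwardsolve(t(R), cxy[S]))
}

## Exhaustive best-subset search over sizes 1..max_size, ranked by an
## information criterion computed from OLS residual sums of squares via
## cross-products (one small Cholesky solve per subset).  Ties on the
## criterion break lexicographically by subset indices.  Returns the top
## n_top distinct subsets.
best_subset_search <- function(X, y, max_size = 10, n_top = 100,
                               criterion = c("bic", "aic"),
                               max_subsets = 5e6) {
  criterion <- match.arg(criterion)
  p <- ncol(X)
  n <- nrow(X)
  max_size <- min(max_size, p, n - 2L)
  total <- sum(choose(p, seq_len(max_size)))
  if (total > max_subsets) {
    stop("subset space too large (", format(total, big.mark = ","),
         "); prescreen predictors first")
  }
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  C <- crossprod(Xc)
  cxy <- as.vector(crossprod(Xc, yc))
  syy <- sum(yc^2)
  const <- n * (log(2 * pi) + 1)   # matches stats::BIC/AIC on lm fits
  pen <- if (criterion == "bic") log(n) else 2

  keep_sub <- list(); keep_crit <- numeric(0); keep_key <- character(0)
  n_skipped <- 0L
  for (k in seq_len(max_size)) {
    cmb <- utils::combn(p, k)
    rss <- vapply(seq_len(ncol(cmb)), function(j) {
      S <- cmb[, j]
      b <- chol_solve_subset(C, cxy, S)
      if (is.null(b)) return(NA_real_)
      max(syy - sum(b * cxy[S]), 0)
    }, numeric(1))
    n_skipped <- n_skipped + sum(is.na(rss))   # NA = singular fit, skipped
    crit <- const + n * log(pmax(rss, 1e-300) / n) + (k + 2) * pen
    crit[is.na(rss)] <- Inf
    key <- apply(cmb, 2, function(S) paste(formatC(S, width = 6, flag = "0"),
                                           collapse = ","))
    ord <- order(crit, key)[seq_len(min(n_top, ncol(cmb)))]
    ord <- ord[is.finite(crit[ord])]
    keep_sub <- c(keep_sub, lapply(ord, function(j) cmb[, j]))
    keep_crit <- c(keep_crit, crit[ord])
    keep_key <- c(keep_key, key[ord])
  }
  ord <- order(keep_crit, keep_key)[seq_len(min(n_top, length(keep_crit)))]
  list(subsets = keep_sub[ord],
       criterion_value = keep_crit[ord],
       criterion = criterion,
       n_skipped = n_skipped,
       n_candidates = total)
}

#' Variance inflation factors for a predictor subset
#'
#' `VIF_j = 1 / (1 - R2_j)`, with `R2_j` from regressing predictor `j` on
#' the other subset members; computed as the diagonal of the inverse
#' correlation matrix.  Size-1 subsets have VIF 1 by convention; a
#' perfectly collinear subset yields `Inf` for all members.
#'
#' @param x a `feature_matrix` or numeric matrix.
#' @param subset column names or indices.
#' @return named numeric vector of VIFs.
#' @export
compute_vif <- function(x, subset = NULL) {
  X <- if (inherits(x, "feature_matrix")) x$X else as.matrix(x)
  if (!is.null(subset)) X <- X[, subset, drop = FALSE]
  nm <- colnames(X) %||% sprintf("x%d", seq_len(ncol(X)))
  if (ncol(X) < 2) return(stats::setNames(rep(1, ncol(X)), nm))
  R <- stats::cor(X)
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv) || any(!is.finite(diag(inv))) || any(diag(inv) < 0)) {
    return(stats::setNames(rep(Inf, ncol(X)), nm))
  }
  stats::setNames(diag(inv), nm)
}

#' Fit the best-subset regression ensemble
#'
#' Enumerates candidate predictor subsets of size 1..`max_size`, ranks the
#' distinct subsets by an information criterion (default BIC, readable as
#' an approximate posterior model weight), refits ordinary least squares
#' on each of the top `n_models` subsets, and averages their per-cell
#' predictions uniformly.  Per-sub-model maximum VIF is recorded and
#' flagged at `vif_threshold`.
#'
#' @param fm a [feature_matrix()].
#' @param max_size maximum predictors per sub-model.
#' @param n_models number of sub-models (fewer if fewer distinct subsets
#'   exist).
#' @param criterion `"bic"` (default) or `"aic"`.
#' @param vif_threshold sub-models with any VIF at or above this are
#'   flagged (flagged, not dropped).
#' @return an object of class `ensemble_fit`.
#' @export
fit_subset_ensemble <- function(fm, max_size = 10, n_models = 100,
                                criterion = "bic", vif_threshold = 5) {
  stopifnot(inherits(fm, "feature_matrix"))
  n <- nrow(fm$X)
  if (n < 5 * max_size) {
    warning("fewer than ", 5 * max_size, " rows for max_size = ", max_size)
  }
  sr <- best_subset_search(fm$X, fm$y, max_size = max_size, n_top = n_models,
                           criterion = criterion)
  xbar <- colMeans(fm$X)
  ybar <- mean(fm$y)
  Xc <- sweep(fm$X, 2, xbar)
  C <- crossprod(Xc)
  cxy <- as.vector(crossprod(Xc, fm$y - ybar))
  members <- vector("list", length(sr$subsets))
  P <- matrix(NA_real_, n, length(sr$subsets))
  for (i in seq_along(sr$subsets)) {
    S <- sr$subsets[[i]]
    b <- chol_solve_subset(C, cxy, S)
    if (is.null(b)) stop("singular refit for a ranked subset")  # unreachable
    a <- ybar - sum(b * xbar[S])
    pred <- a + as.vector(fm$X[, S, drop = FALSE] %*% b)
    vif <- compute_vif(fm$X, S)
    members[[i]] <- list(
      predictors = colnames(fm$X)[S],
      coefficients = c("(Intercept)" = a,
                       stats::setNames(b, colnames(fm$X)[S])),
      criterion_value = sr$criterion_value[i],
      size = length(S),
      max_vif = max(vif),
      vif_flag = max(vif) >= vif_threshold)
    P[, i] <- pred
  }
  structure(list(
    submodels = members,
    predictor_set = fm$predictor_set %||% "custom",
    member_predictions = P,
    mean_prediction = rowMeans(P),
    criterion = criterion,
    n_models = length(members),
    n_candidate_subsets = sr$n_candidates,
    n_skipped = sr$n_skipped,
    y = fm$y,
    cell_id = fm$cell_id,
    center = fm$center,
    scale = fm$scale,
    vif_threshold = vif_threshold
  ), class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat("Best-subset ensemble (", x$predictor_set, "): ", x$n_models,
      " sub-models, criterion ", toupper(x$criterion), "\n", sep = "")
  cat("  fit R2:",
      round(coefficient_of_determination(x$y, x$mean_prediction), 3), "\n")
  cat("  sub-models with VIF >=", x$vif_threshold, ":",
      sum(vapply(x$submodels, `[[`, logical(1), "vif_flag")), "\n")
  invisible(x)
}

#' Ensemble prediction for new cells
#'
#' Averages the sub-model predictions uniformly.  `new_features` must
#' contain every predictor used by any sub-model; raw (unscaled) features
#' are transformed with the scaling parameters stored at training time.
#'
#' @param ensemble an [fit_subset_ensemble()] result.
#' @param new_features data.frame or matrix of predictor columns.
#' @param scaled set TRUE if `new_features` are already on the training
#'   z-scale.
#' @return list with `point` (per-cell mean prediction) and `members`
#'   (cells x sub-models prediction matrix).
#' @export
ensemble_predict <- function(ensemble, new_features, scaled = FALSE) {
  used <- unique(unlist(lapply(ensemble$submodels, `[[`, "predictors")))
  X <- as.matrix(as.data.frame(new_features)[,
         intersect(colnames(as.data.frame(new_features)), used),
         drop = FALSE])
  missing_cols <- setdiff(used, colnames(X))
  if (length(missing_cols)) {
    stop("missing predictor columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!scaled) {
    X <- sweep(sweep(X, 2, ensemble$center[colnames(X)]), 2,
               ensemble$scale[colnames(X)], "/")
  }
  P <- vapply(ensemble$submodels, function(m) {
    cf <- m$coefficients
    cf[["(Intercept)"]] +
      as.vector(X[, m$predictors, drop = FALSE] %*%
                  cf[m$predictors])
  }, numeric(nrow(X)))
  P <- matrix(P, nrow = nrow(X))
  list(point = rowMeans(P), members = P)
}

#' Selection-frequency summary of an ensemble
#'
#' For every predictor selected in at least one sub-model: the mean of its
#' coefficient estimates across the sub-models containing it, the SD of
#' those estimates (reported as `NA` when selected only once), and the
#' number of sub-models in which it was selected.  Sorted by selection
#' count.  The intercept row is included; with predictors standardized to
#' mean zero its estimate is constant at the training-mean response.
#'
#' @param ensemble an [fit_subset_ensemble()] result.
#' @return data.frame `predictor`, `mean_estimate`, `sd_estimate`,
#'   `n_models`.
#' @export
selection_summary <- function(ensemble) {
  cf <- unlist(lapply(ensemble$submodels, `[[`, "coefficients"))
  nm <- names(cf)
  est <- split(unname(cf), nm)
  out <- data.frame(
    predictor = names(est),
    mean_estimate = vapply(est, mean, numeric(1)),
    sd_estimate = vapply(est, function(v) {
      if (length(v) == 1) NA_real_ else stats::sd(v)
    }, numeric(1)),
    n_models = vapply(est, length, integer(1))
  )
  out <- out[order(-out$n_models, -abs(out$mean_estimate)), ]
  ## intercept first, mirroring the conventional summary table layout
  ic <- out$predictor == "(Intercept)"
  out <- rbind(out[ic, ], out[!ic, ])
  rownames(out) <- NULL
  out
}

#' Two-step predictor pre-screen
#'
#' With many candidate predictors, exhaustive subset search is infeasible;
#' this screen (step 1) partitions the predictors into blocks of at most
#' `block_size`, runs the best-subset search within each block, and
#' retains predictors selected in at least one of the block's `keep_top`
#' top-ranked subsets; (step 2) pools the retained predictors for the main
#' ensemble, repeating the block screen while the pool still exceeds
#' `block_size`.
#'
#' @param fm a [feature_matrix()].
#' @param block_size largest predictor count handled exhaustively.
#' @param max_size maximum subset size used in the screen (must be <=
#'   `block_size`).
#' @param keep_top number of top subsets per block whose union is retained.
#' @return the reduced `feature_matrix`; attribute `"screen"` lists
#'   retained and dropped predictors.
#' @export
prescreen_predictors <- function(fm, block_size = 15, max_size = 10,
                                 keep_top = 5) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (block_size < max_size) {
    stop("block_size must be at least max_size")
  }
  all_pred <- colnames(fm$X)
  retained <- all_pred
  guard <- 0L
  while (length(retained) > block_size && guard < 10L) {
    guard <- guard + 1L
    blocks <- split(retained, ceiling(seq_along(retained) / block_size))
    new_ret <- character(0)
    for (bl in blocks) {
      Xb <- fm$X[, bl, drop = FALSE]
      sr <- best_subset_search(Xb, fm$y,
                               max_size = min(max_size, length(bl)),
                               n_top = keep_top)
      new_ret <- c(new_ret, bl[sort(unique(unlist(sr$subsets)))])
    }
    new_ret <- retained[retained %in% new_ret]   # preserve column order
    if (length(new_ret) == length(retained)) break
    retained <- new_ret
  }
  out <- fm_select_predictors(fm, retained)
  attr(out, "screen") <- list(retained = retained,
                              dropped = setdiff(all_pred, retained))
  out
}

#' Sensitivity of the ensemble fit to the predictor pre-screen
#'
#' Fits the ensemble on the screened and the unscreened predictor set and
#' reports both fit R-squared values and their difference.  Only feasible
#' when the unscreened subset space is enumerable, so keep `max_size`
#' and/or the number of predictors moderate.
#'
#' @inheritParams prescreen_predictors
#' @param n_models sub-models per ensemble.
#' @return list `r2_screened`, `r2_unscreened`, `delta_r2`, `n_retained`.
#' @export
prescreen_sensitivity <- function(fm, block_size = 15, max_size = 5,
                                  keep_top = 5, n_models = 100) {
  fm_s <- prescreen_predictors(fm, block_size = block_size,
                               max_size = max_size, keep_top = keep_top)
  e_s <- fit_subset_ensemble(fm_s, max_size = max_size, n_models = n_models)
  e_u <- fit_subset_ensemble(fm, max_size = max_size, n_models = n_models)
  r2s <- coefficient_of_determination(fm$y, e_s$mean_prediction)
  r2u <- coefficient_of_determination(fm$y, e_u$mean_prediction)
  list(r2_screened = r2s, r2_unscreened = r2u, delta_r2 = r2s - r2u,
       n_retained = ncol(fm_s$X))
}
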
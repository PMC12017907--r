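#' Coefficient of determination (1 - SSE/SST)
#'
#' Defined against the observed mean, not as a squared correlation, so
#' out-of-fold values can be negative when predictions do worse than the
#' mean.
#'
#' @param obs,pred numeric vectors of equal length (>= 2).
#' @return a single number, at most 1, possibly negative.
#' @export
coefficient_of_determination <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("obs and pred lengths differ")
  if (length(obs) < 2) stop("need at least 2 observations")
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("zero variance in obs; R-squared undefined")
  1 - sum((obs - pred)^2) / sst
}

#' Five-fold cross-validation of the subset-ensemble pipeline
#'
#' Randomly partitions the cells into `k` folds (sizes within one of
#' `n/k`), re-runs the full modeling procedure — optional predictor
#' pre-screen plus best-subset ensemble — on each training split, and
#' assembles out-of-fold predictions for every cell.  Validation
#' R-squared is `1 - SSE/SST` on the out-of-fold predictions; fit
#' R-squared comes from the full-data ensemble.
#'
#' @param fm a [feature_matrix()] (scaled once on the full data; the fold
#'   re-runs reuse that scale, matching a single upfront standardization).
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @param max_size,n_models,criterion passed to [fit_subset_ensemble()].
#' @param prescreen run [prescreen_predictors()] inside each training
#'   split.
#' @param block_size,keep_top pre-screen settings.
#' @return list of class `cv_result`: `oof_prediction`, `fold`, `fit_r2`,
#'   `validation_r2`, `pearson_r`, `cell_id`, `obs`.
#' @export
kfold_cv <- function(fm, k = 5, seed = NULL, max_size = 10, n_models = 100,
                     criterion = "bic", prescreen = FALSE,
                     block_size = 15, keep_top = 5) {
  stopifnot(inherits(fm, "feature_matrix"))
  n <- nrow(fm$X)
  if (k > n) stop("k exceeds the number of cells")
  fold <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  oof <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train_fm <- fm_subset_rows(fm, setdiff(seq_len(n), test))
    if (prescreen && ncol(train_fm$X) > block_size) {
      train_fm <- prescreen_predictors(train_fm, block_size = block_size,
                                       max_size = max_size,
                                       keep_top = keep_top)
    }
    ens <- fit_subset_ensemble(train_fm, max_size = max_size,
                               n_models = n_models, criterion = criterion)
    pr <- ensemble_predict(ens, fm$X[test, , drop = FALSE], scaled = TRUE)
    oof[test] <- pr$point
  }
  full_fm <- fm
  if (prescreen && ncol(full_fm$X) > block_size) {
    full_fm <- prescreen_predictors(full_fm, block_size = block_size,
                                    max_size = max_size, keep_top = keep_top)
  }
  full <- fit_subset_ensemble(full_fm, max_size = max_size,
                              n_models = n_models, criterion = criterion)
  structure(list(
    oof_prediction = oof,
    fold = fold,
    fit_r2 = coefficient_of_determination(fm$y, full$mean_prediction),
    validation_r2 = coefficient_of_determination(fm$y, oof),
    pearson_r = stats::cor(fm$y, oof),
    cell_id = fm$cell_id,
    obs = fm$y,
    full_ensemble = full
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Five-fold CV:", length(x$obs), "cells\n")
  cat("  fit R2:       ", round(x$fit_r2, 3), "\n")
  cat("  validation R2:", round(x$validation_r2, 3), "\n")
  invisible(x)
}

#' Compare two dependent, overlapping correlations
#'
#' Tests whether `cor(obs, predA)` differs from `cor(obs, predB)` when
#' both are computed on the same cells, accounting for the correlation
#' between the two predictions.  Default statistic: the Dunn-Clark z with
#' the backtransformed-average modification (the variant recommended in
#' the methods-comparison literature for overlapping correlations);
#' `method = "dunn1969"` uses the raw correlations in the covariance
#' term instead.
#'
#' @param obs,predA,predB equal-length numeric vectors, n >= 10.
#' @param method `"hittner2003"` (default) or `"dunn1969"`.
#' @return list of class `correlation_comparison`: the three correlations,
#'   `n`, `z`, two-sided `p`, and `test` = `"dependent_overlapping"`.
#' @export
compare_dependent_correlations <- function(obs, predA, predB,
                                           method = c("hittner2003",
                                                      "dunn1969")) {
  method <- match.arg(method)
  n <- length(obs)
  if (length(predA) != n || length(predB) != n) stop("length mismatch")
  if (n < 10) stop("need n >= 10")
  if (stats::sd(obs) == 0 || stats::sd(predA) == 0 || stats::sd(predB) == 0) {
    stop("constant vector; correlations undefined")
  }
  r12 <- stats::cor(obs, predA)
  r13 <- stats::cor(obs, predB)
  r23 <- stats::cor(predA, predB)
  z12 <- atanh(r12)
  z13 <- atanh(r13)
  if (method == "hittner2003") {
    rm_ <- tanh((z12 + z13) / 2)   # backtransformed average correlation
    cnum <- r23 * (1 - 2 * rm_^2) - 0.5 * rm_^2 * (1 - 2 * rm_^2 - r23^2)
    cden <- (1 - rm_^2)^2
  } else {
    cnum <- r23 * (1 - r12^2 - r13^2) -
      0.5 * r12 * r13 * (1 - r12^2 - r13^2 - r23^2)
    cden <- (1 - r12^2) * (1 - r13^2)
  }
  cv <- cnum / cden
  ## equal correlations give z = 0 even when the variance term degenerates
  ## (e.g. identical predictions, where cv -> 1)
  z <- if (z12 == z13) 0 else {
    (z12 - z13) * sqrt((n - 3) / max(2 - 2 * cv, .Machine$double.eps))
  }
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(r_obs_predA = r12, r_obs_predB = r13,
                 r_predA_predB = r23, n = n, z = z, p = p,
                 method = method, test = "dependent_overlapping"),
            class = "correlation_comparison")
}

#' Compare two independent correlations (Fisher z)
#'
#' Two-sample test for correlations estimated on independent datasets,
#' e.g. the same model family fit to two different study regions.
#'
#' @param rA,rB sample correlations, strictly inside (-1, 1).
#' @param nA,nB sample sizes (>= 4).
#' @return list of class `correlation_comparison` with `z`, two-sided `p`,
#'   and `test` = `"independent"`.
#' @export
compare_independent_correlations <- function(rA, nA, rB, nB) {
  if (abs(rA) >= 1 || abs(rB) >= 1) stop("|r| must be < 1")
  if (nA < 4 || nB < 4) stop("need n >= 4 in both samples")
  z <- (atanh(rA) - atanh(rB)) / sqrt(1 / (nA - 3) + 1 / (nB - 3))
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(r_obs_predA = rA, r_obs_predB = rB,
                 r_predA_predB = NA_real_, n = c(nA, nB), z = z, p = p,
                 method = "fisher_z", test = "independent"),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat("Correlation comparison (", x$test, ", ", x$method, ")\n", sep = "")
  cat(sprintf("  rA = %.3f, rB = %.3f, z = %.3f, p = %.4g\n",
              x$r_obs_predA, x$r_obs_predB, x$z, x$p))
  invisible(x)
}
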
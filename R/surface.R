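#' Predict bee richness across an extent
#'
#' Applies the fitted ensemble to a table of per-cell extent features
#' (land-cover percentages plus per-species abundance or residual
#' surfaces), returning the per-cell mean over sub-model predictions and
#' the member-prediction matrix for uncertainty.
#'
#' @param ensemble an [fit_subset_ensemble()] result.
#' @param extent_features data.frame with a `cell_id` column (and optional
#'   `x`, `y`) plus every predictor any sub-model uses, on the raw
#'   (unscaled) scale used at training.
#' @param scaled set TRUE if features are already on the training z-scale.
#' @return list with `cells` (data.frame `cell_id`, `x`, `y`,
#'   `point_estimate`) and `members` (cells x sub-models matrix).
#' @export
predict_extent <- function(ensemble, extent_features, scaled = FALSE) {
  ef <- as.data.frame(extent_features)
  pr <- ensemble_predict(ensemble, ef, scaled = scaled)
  data_cols <- data.frame(
    cell_id = ef$cell_id %||% as.character(seq_len(nrow(ef))),
    x = ef$x %||% NA_real_,
    y = ef$y %||% NA_real_,
    point_estimate = pr$point)
  list(cells = data_cols, members = pr$members)
}

#' Scaled uncertainty of an ensemble prediction surface
#'
#' Per cell, the width of the empirical 90% interval (5th to 95th
#' percentile, linear interpolation; or mean +/- 1.645 SD with
#' `ci_method = "normal"`) of the sub-model predictions, normalized by the
#' range of point estimates across all cells and expressed as a
#' percentage.  Cells whose sub-models agree exactly get 0%.
#'
#' @param members cells x sub-models prediction matrix (>= 2 members).
#' @param ci_method `"percentile"` (default) or `"normal"`.
#' @return list with `ci90_low`, `ci90_high`, `scaled_uncertainty_pct` per
#'   cell.
#' @export
scaled_uncertainty <- function(members, ci_method = c("percentile",
                                                      "normal")) {
  ci_method <- match.arg(ci_method)
  members <- as.matrix(members)
  if (ncol(members) < 2) stop("need at least 2 ensemble members")
  point <- rowMeans(members)
  rng <- max(point) - min(point)
  if (rng == 0) stop("all point estimates identical; normalizer undefined")
  if (ci_method == "percentile") {
    qs <- t(apply(members, 1, stats::quantile, probs = c(0.05, 0.95),
                  type = 7, names = FALSE))
    lo <- qs[, 1]; hi <- qs[, 2]
  } else {
    s <- apply(members, 1, stats::sd)
    lo <- point - 1.645 * s
    hi <- point + 1.645 * s
  }
  list(ci90_low = lo, ci90_high = hi,
       scaled_uncertainty_pct = 100 * (hi - lo) / rng)
}

#' Prediction and uncertainty surface for an extent
#'
#' Convenience wrapper combining [predict_extent()] and
#' [scaled_uncertainty()] into one cell-keyed table ready for mapping.
#'
#' @inheritParams predict_extent
#' @inheritParams scaled_uncertainty
#' @return data.frame `cell_id`, `x`, `y`, `point_estimate`, `ci90_low`,
#'   `ci90_high`, `scaled_uncertainty_pct`.
#' @export
build_surface <- function(ensemble, extent_features, scaled = FALSE,
                          ci_method = "percentile") {
  pe <- predict_extent(ensemble, extent_features, scaled = scaled)
  un <- scaled_uncertainty(pe$members, ci_method = ci_method)
  out <- pe$cells
  out$ci90_low <- un$ci90_low
  out$ci90_high <- un$ci90_high
  out$scaled_uncertainty_pct <- un$scaled_uncertainty_pct
  out
}
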
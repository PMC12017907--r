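make_fm <- function(n = 60, p = 8, betas = c(x1 = 0.5, x3 = -0.4),
                    noise = 1, seed = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- 1 + as.vector(X[, names(betas), drop = FALSE] %*% betas) +
    rnorm(n, 0, noise)
  feature_matrix(X, y)
}

## brute-force ranked subset list via lm() + stats::BIC, ties broken
## lexicographically by subset indices — the independent oracle
brute_force_subsets <- function(fm, max_size) {
  p <- ncol(fm$X)
  subs <- unlist(lapply(seq_len(max_size), combn, x = p,
                        simplify = FALSE), recursive = FALSE)
  bic <- vapply(subs, function(S) {
    stats::BIC(stats::lm(fm$y ~ fm$X[, S, drop = FALSE]))
  }, numeric(1))
  key <- vapply(subs, function(S) {
    paste(formatC(S, width = 6, flag = "0"), collapse = ",")
  }, character(1))
  ord <- order(bic, key)
  list(subsets = subs[ord], bic = bic[ord])
}

test_that("ensemble ranking equals brute-force enumeration (property, several seeds)", {
  for (seed in c(3, 8, 15)) {
    fm <- make_fm(n = 50, p = 7, seed = seed)
    ens <- fit_subset_ensemble(fm, max_size = 3, n_models = 100)
    oracle <- brute_force_subsets(fm, max_size = 3)
    expect_equal(length(ens$submodels), length(oracle$subsets))
    mine <- lapply(ens$submodels, function(m) match(m$predictors,
                                                   colnames(fm$X)))
    expect_identical(mine, oracle$subsets)
    expect_equal(vapply(ens$submodels, `[[`, numeric(1), "criterion_value"),
                 oracle$bic, tolerance = 1e-10)
  }
})

test_that("sub-model coefficients equal the OLS refit", {
  fm <- make_fm()
  ens <- fit_subset_ensemble(fm, max_size = 3, n_models = 5)
  for (m in ens$submodels) {
    ref <- stats::lm(fm$y ~ fm$X[, m$predictors, drop = FALSE])
    expect_equal(unname(m$coefficients), unname(coef(ref)),
                 tolerance = 1e-10)
  }
})

test_that("noiseless linear truth is recovered exactly by the top sub-model", {
  fm <- make_fm(n = 80, p = 6, betas = c(x2 = 1, x5 = -2), noise = 0)
  ens <- fit_subset_ensemble(fm, max_size = 3, n_models = 3)
  expect_setequal(ens$submodels[[1]]$predictors, c("x2", "x5"))
  pred <- ens$member_predictions[, 1]
  expect_lt(sum((fm$y - pred)^2), 1e-16)
})

test_that("n_models = 1 reduces the ensemble to a single OLS prediction", {
  fm <- make_fm()
  ens <- fit_subset_ensemble(fm, max_size = 3, n_models = 1)
  expect_equal(ens$mean_prediction, ens$member_predictions[, 1])
})

test_that("intercepts equal the training mean response on standardized features", {
  fm <- make_fm(n = 100, p = 10)
  ens <- fit_subset_ensemble(fm, max_size = 4, n_models = 100)
  ints <- vapply(ens$submodels, function(m) m$coefficients[["(Intercept)"]],
                 numeric(1))
  expect_true(all(abs(ints - mean(fm$y)) < 1e-8))
})

test_that("VIF matches independent regressions and closed forms", {
  set.seed(9)
  n <- 400
  ## orthogonal mean-zero columns -> exactly 1
  Xo <- orthonormal_cols(n, 4)
  colnames(Xo) <- paste0("o", 1:4)
  expect_equal(unname(compute_vif(Xo)), rep(1, 4), tolerance = 1e-10)
  ## pair with sample correlation exactly 0.8 -> 1/(1-0.64)
  z <- orthonormal_cols(n, 2)
  x1 <- z[, 1]
  x2 <- 0.8 * z[, 1] + sqrt(1 - 0.64) * z[, 2]
  X <- cbind(a = x1, b = x2)
  expect_equal(unname(compute_vif(X)), rep(1 / (1 - 0.64), 2),
               tolerance = 1e-10)
  ## against independent lm regressions on a general matrix
  Xg <- matrix(rnorm(n * 5), n, 5) %*% chol(0.5 + 0.5 * diag(5))
  colnames(Xg) <- paste0("g", 1:5)
  v <- compute_vif(Xg)
  for (j in 1:5) {
    r2 <- summary(stats::lm(Xg[, j] ~ Xg[, -j]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-10)
  }
  ## duplicated column -> infinite VIF flag; singletons are 1 by convention
  expect_true(all(is.infinite(compute_vif(cbind(d1 = x1, d2 = x1)))))
  expect_equal(unname(compute_vif(Xg, subset = "g1")), 1)
})

test_that("ensembles record and flag sub-model VIF at the threshold", {
  set.seed(10)
  n <- 200
  x1 <- rnorm(n)
  x2 <- x1 + rnorm(n, 0, 0.3)   # strongly collinear pair
  X <- cbind(a = x1, b = x2, c = rnorm(n))
  y <- x1 + x2 + rnorm(n)
  ens <- fit_subset_ensemble(feature_matrix(X, y), max_size = 3,
                             n_models = 7, vif_threshold = 5)
  flags <- vapply(ens$submodels, `[[`, logical(1), "vif_flag")
  both <- vapply(ens$submodels, function(m) {
    all(c("a", "b") %in% m$predictors)
  }, logical(1))
  expect_equal(flags, vapply(ens$submodels, function(m) m$max_vif >= 5,
                             logical(1)))
  expect_true(all(flags[both]))
  expect_false(any(flags[!both]))
})

test_that("ensemble prediction is the uniform member mean", {
  fm <- make_fm()
  ens <- fit_subset_ensemble(fm, max_size = 3, n_models = 10)
  pr <- ensemble_predict(ens, fm$X, scaled = TRUE)
  expect_equal(pr$point, rowMeans(pr$members), tolerance = 1e-12)
  expect_equal(pr$point, ens$mean_prediction, tolerance = 1e-12)
  ## two members predicting 3 and 5 average to 4
  toy <- ens
  toy$submodels <- list(
    list(predictors = "x1", coefficients = c("(Intercept)" = 3, x1 = 0)),
    list(predictors = "x1", coefficients = c("(Intercept)" = 5, x1 = 0)))
  expect_equal(ensemble_predict(toy, fm$X, scaled = TRUE)$point,
               rep(4, nrow(fm$X)))
  expect_error(ensemble_predict(ens, fm$X[, 1:2]), "missing predictor")
})

test_that("raw-scale prediction applies the stored training transform", {
  set.seed(12)
  X <- matrix(rnorm(50 * 4, mean = 10, sd = 3), 50, 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  y <- 2 + X[, 1] + rnorm(50)
  fm <- feature_matrix(X, y)
  ens <- fit_subset_ensemble(fm, max_size = 2, n_models = 5)
  expect_equal(ensemble_predict(ens, X)$point,
               ensemble_predict(ens, fm$X, scaled = TRUE)$point,
               tolerance = 1e-12)
})

test_that("selection summary reports counts, means and absent SDs", {
  fm <- make_fm(n = 100, p = 6)
  ens <- fit_subset_ensemble(fm, max_size = 3, n_models = 20)
  ss <- selection_summary(ens)
  expect_equal(ss$predictor[1], "(Intercept)")
  expect_equal(ss$n_models[1], ens$n_models)
  expect_equal(ss$sd_estimate[1], 0)
  ## double-counting identity: selection counts sum to total subset sizes
  sizes <- vapply(ens$submodels, `[[`, integer(1), "size")
  expect_equal(sum(ss$n_models[ss$predictor != "(Intercept)"]), sum(sizes))
  ## a predictor selected once has no SD
  if (any(ss$n_models == 1)) {
    expect_true(all(is.na(ss$sd_estimate[ss$n_models == 1])))
  }
  ## per-predictor mean matches manual pooling
  for (p in ss$predictor[-1][1:2]) {
    est <- unlist(lapply(ens$submodels, function(m) m$coefficients[p]))
    est <- est[!is.na(est)]
    expect_equal(ss$mean_estimate[ss$predictor == p], mean(est))
  }
})

test_that("feature matrix construction scales, joins and restricts correctly", {
  cr <- data.frame(cell_id = c("A", "B", "C", "D"), richness = 1:4)
  lc <- data.frame(cell_id = c("A", "B", "C", "E"),
                   crop = c(10, 20, 30, 40), forest = c(90, 80, 70, 60))
  bf <- data.frame(cell_id = rep(c("A", "B", "C"), 2),
                   species = rep(c("sp1", "sp2"), each = 3),
                   mean_residual = c(0.1, -0.2, 0.3, 0, 0.5, -0.5))
  fm <- build_feature_matrix(cr, lc, bf, "birds_and_landcover")
  expect_setequal(fm$cell_id, c("A", "B", "C"))   # intersection only
  expect_setequal(colnames(fm$X), c("crop", "forest", "sp1", "sp2"))
  expect_equal(unname(colMeans(fm$X)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(fm$X, 2, sd)), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(fm$provenance),
               c("landcover", "landcover", "bird", "bird"))
  fm_lc <- build_feature_matrix(cr, lc, bf, "landcover_only")
  expect_setequal(colnames(fm_lc$X), c("crop", "forest"))
  ## landcover-only still restricts to the triple intersection
  expect_setequal(fm_lc$cell_id, c("A", "B", "C"))
})

test_that("zero-variance predictors are dropped with a warning", {
  set.seed(2)
  X <- cbind(a = rnorm(30), b = rep(1, 30))
  expect_warning(fm <- feature_matrix(X, rnorm(30)), "zero-variance")
  expect_equal(colnames(fm$X), "a")
})

test_that("prescreen is the identity below the block size and errors on bad config", {
  fm <- make_fm(n = 100, p = 8)
  out <- prescreen_predictors(fm, block_size = 10, max_size = 5)
  expect_identical(colnames(out$X), colnames(fm$X))
  expect_error(prescreen_predictors(fm, block_size = 3, max_size = 5),
               "block_size")
})

test_that("prescreen removes most pure-noise decoys while keeping signal", {
  removed <- numeric(3)
  kept_true <- logical(3)
  for (i in 1:3) {
    set.seed(100 + i)
    n <- 500; p <- 24
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- 0.6 * X[, 1] - 0.5 * X[, 13] + rnorm(n)
    fm <- feature_matrix(X, y)
    out <- prescreen_predictors(fm, block_size = 12, max_size = 6)
    scr <- attr(out, "screen")
    kept_true[i] <- all(c("x1", "x13") %in% scr$retained)
    removed[i] <- length(setdiff(scr$dropped, c("x1", "x13"))) / (p - 2)
  }
  expect_true(all(kept_true))
  expect_gt(mean(removed), 0.5)
})

test_that("screening changes the ensemble fit negligibly on synthetic truth", {
  set.seed(31)
  n <- 400; p <- 18
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- 0.5 * X[, 2] + 0.4 * X[, 11] - 0.3 * X[, 17] + rnorm(n)
  fm <- feature_matrix(X, y)
  sens <- prescreen_sensitivity(fm, block_size = 9, max_size = 4,
                                n_models = 50)
  expect_lt(abs(sens$delta_r2), 0.02)
})
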
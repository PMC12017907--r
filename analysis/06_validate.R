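## Five-fold cross-validation of each predictor set and pairwise
## dependent-correlation tests of which set predicts observed richness
## best.

source("analysis/00_config.R")

cvs <- list()
rows <- list()
for (ps in PREDICTOR_SETS) {
  st <- readRDS(file.path(DERIVED_DIR, sprintf("ensemble_%s.rds", ps)))
  cv <- kfold_cv(st$fm, k = 5, seed = STUDY_SEED, max_size = 10,
                 n_models = 100)
  cvs[[ps]] <- cv
  rows[[ps]] <- data.frame(predictor_set = ps,
                           fit_r2 = cv$fit_r2,
                           validation_r2 = cv$validation_r2,
                           pearson_r = cv$pearson_r)
  cat(sprintf("%-20s fit R2 = %5.3f  validation R2 = %5.3f\n",
              ps, cv$fit_r2, cv$validation_r2))
}
write.csv(do.call(rbind, rows),
          file.path(RESULTS_DIR, "validation.csv"), row.names = FALSE)

## pairwise comparisons on the shared cells (out-of-fold predictions)
obs <- cvs[[1]]$obs
pairs <- combn(PREDICTOR_SETS, 2, simplify = FALSE)
cmp_rows <- lapply(pairs, function(pr) {
  a <- cvs[[pr[1]]]; b <- cvs[[pr[2]]]
  stopifnot(identical(a$cell_id, b$cell_id))
  cc <- compare_dependent_correlations(a$obs, a$oof_prediction,
                                       b$oof_prediction)
  cat(sprintf("%s vs %s: rA = %.3f rB = %.3f z = %.2f p = %.4g\n",
              pr[1], pr[2], cc$r_obs_predA, cc$r_obs_predB, cc$z, cc$p))
  data.frame(set_a = pr[1], set_b = pr[2],
             r_obs_a = cc$r_obs_predA, r_obs_b = cc$r_obs_predB,
             r_a_b = cc$r_predA_predB, z = cc$z, p = cc$p)
})
write.csv(do.call(rbind, cmp_rows),
          file.path(RESULTS_DIR, "correlation_comparisons.csv"),
          row.names = FALSE)

saveRDS(cvs, file.path(DERIVED_DIR, "cv_results.rds"))
cat("Wrote", file.path(RESULTS_DIR, "validation.csv"), "and",
    file.path(RESULTS_DIR, "correlation_comparisons.csv"), "\n")
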
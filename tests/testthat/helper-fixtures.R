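## Shared fixtures, all built in code.

## Ten bee occurrence records exercising every record-level exclusion rule:
## rows 4 and 7 duplicate rows 3 and 6, row 5 lacks a species, row 9 has
## 4 km coordinate uncertainty -> 6 retained.
toy_bee_records <- function() {
  data.frame(
    species = c("Bombus impatiens", "Andrena nasonii", "Halictus ligatus",
                "Halictus ligatus", NA, "Lasioglossum pilosum",
                "Lasioglossum pilosum", "Bombus impatiens",
                "Megachile rotundata", "Agapostemon virescens"),
    latitude = c(1.1, 1.2, 4.1, 4.1, 1.3, 7.5, 7.5, 7.6, 1.4, 4.3),
    longitude = c(2.0, 2.1, 2.2, 2.2, 2.3, 5.0, 5.0, 5.1, 2.4, 5.2),
    date = c("2021-06-01", "2021-06-01", "2021-06-02", "2021-06-02",
             "2021-06-03", "2021-06-04", "2021-06-04", "2021-06-04",
             "2021-06-05", "2021-06-06"),
    coord_uncertainty_km = c(0.5, 1, 2, 2, 0.5, 1, 1, 1, 4, 0.2),
    survey_id = paste0("s", c(1, 2, 3, 3, 4, 5, 5, 5, 6, 7))
  )
}

## A long checklist table with known composition for the filter test:
## 12 checklists; 2 off-season, 1 too short (4 min), and one observer with
## only 2 (retained-eligible) checklists -> 6 survive all rules.
toy_checklists <- function() {
  eff <- data.frame(
    checklist_id = sprintf("c%02d", 1:12),
    cell_id = rep(c("g0_0", "g1_0", "g0_1"), each = 4),
    observer_id = c(rep("obsA", 6), rep("obsB", 4), "obsC", "obsC"),
    date = c(rep("2021-06-10", 4), "2021-04-01", "2021-09-01",
             rep("2021-07-01", 6)),
    duration_min = c(60, 30, 4, 120, 60, 60, 45, 90, 60, 30, 60, 60),
    distance_km = c(1, 0, 2, 3, 1, 1, 0.5, 2, 1, 0, 1, 2),
    start_time = c(7, 8, 9, 10, 7, 7, 6, 8, 9, 10, 7, 8),
    protocol = c(rep("traveling", 6), "stationary", rep("traveling", 5)),
    all_species_reported = TRUE
  )
  long <- merge(eff, expand.grid(checklist_id = eff$checklist_id,
                                 species = c("spA", "spB"),
                                 stringsAsFactors = FALSE))
  long$count <- seq_len(nrow(long)) %% 4
  long
}

small_config <- function(seed = 1L, ...) {
  synth_config(n_cells = 40, n_landcover_classes = 4, n_bird_species = 3,
               n_true_predictors = 2, seed = seed, ...)
}

## orthonormal mean-zero columns: sample correlations are exactly zero
orthonormal_cols <- function(n, k) {
  M <- scale(matrix(stats::rnorm(n * k), n, k), center = TRUE, scale = FALSE)
  qr.Q(qr(M))
}

## trivariate normal draws with obs/predA, obs/predB correlation rho_y and
## predA/predB correlation rho_x: the null of the dependent-correlation test
rmvnorm3 <- function(n, rho_y = 0.5, rho_x = 0.7) {
  Sig <- matrix(c(1, rho_y, rho_y,
                  rho_y, 1, rho_x,
                  rho_y, rho_x, 1), 3, 3)
  matrix(stats::rnorm(3 * n), n, 3) %*% chol(Sig)
}
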
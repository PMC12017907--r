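## Shared settings for the analysis scripts.  Source from the repository
## root; intermediates go under scratch/ (regenerated by running the
## scripts in order), small result tables under results/.

library(beerich)

STUDY_SEED <- 2026L

## The simulated study system: 400 grid cells, 8 land-cover classes,
## 12 bird species, 5 true predictors at moderate effect sizes, and
## noise matched to the signal (theoretical R2 = 0.5).
study_config <- function(seed = STUDY_SEED) {
  synth_config(n_cells = 400L,
               n_landcover_classes = 8L,
               n_bird_species = 12L,
               n_true_predictors = 5L,
               true_coefficients = c(0.5, -0.4, 0.4, -0.35, 0.3),
               surveys_per_cell_range = c(3L, 8L),
               checklists_per_cell_range = c(6L, 14L),
               seed = seed)
}

DATA_DIR <- "scratch/analysis/data"
DERIVED_DIR <- "scratch/analysis/derived"
RESULTS_DIR <- "results"
for (d in c(DATA_DIR, DERIVED_DIR, RESULTS_DIR)) {
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
}

PREDICTOR_SETS <- c("landcover_only", "birds_only", "birds_and_landcover")
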
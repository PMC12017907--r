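## Standardize bird abundance for survey effort: filter checklists, fit a
## per-species GAM of counts on duration, distance and start time, take
## log-scale residuals, and average them per grid cell.  Then apply the
## prevalence filter to pick the candidate species.

source("analysis/00_config.R")

cl_raw <- read.csv(file.path(DATA_DIR, "checklists.tsv"), sep = "\t")

cl <- filter_checklists(cl_raw)
cat("Checklists retained:", length(unique(cl$checklist_id)), "of",
    length(unique(cl_raw$checklist_id)), "\n")

prev <- species_prevalence_filter(cl)   # no range maps in the simulation
cat("Species passing the 20% prevalence screen:",
    sum(prev$retained), "of", nrow(prev), "\n")
write.csv(prev, file.path(RESULTS_DIR, "bird_species_screen.csv"),
          row.names = FALSE)

species <- prev$species[prev$retained]
features <- bird_cell_features(cl, species)
cat("Cell x species residual features:", nrow(features), "rows,",
    length(unique(features$species)), "species\n")
cat("  per-species mean residual (should be ~0):",
    round(max(abs(tapply(features$mean_residual, features$species, mean))), 4),
    "max abs\n")

write.csv(features, file.path(DERIVED_DIR, "bird_features.csv"),
          row.names = FALSE)
cat("Wrote", file.path(DERIVED_DIR, "bird_features.csv"), "\n")
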
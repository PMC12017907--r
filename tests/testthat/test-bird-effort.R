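test_that("checklist filter enforces season, duration, protocol, observer rules", {
  cl <- toy_checklists()
  out <- filter_checklists(cl)
  kept <- sort(unique(out$checklist_id))
  ## c03 too short, c05/c06 off-season, c11/c12 from a 2-checklist observer
  expect_equal(kept, sprintf("c%02d", c(1, 2, 4, 7, 8, 9, 10)))
  ## observer with exactly 3 surviving checklists is retained (>= 3)
  expect_true("obsA" %in% out$observer_id)
})

test_that("checklists with non-numeric (presence-only) counts are dropped whole", {
  cl <- toy_checklists()
  cl$count <- as.character(cl$count)
  cl$count[cl$checklist_id == "c01"][1] <- "X"
  out <- filter_checklists(cl)
  expect_false("c01" %in% out$checklist_id)
  expect_type(out$count, "double")
})

test_that("effort model is near-constant when counts carry no effort signal", {
  set.seed(21)
  n <- 2000
  eff <- data.frame(
    checklist_id = sprintf("c%04d", 1:n), cell_id = "g",
    observer_id = "o", date = "2021-06-01",
    duration_min = exp(runif(n, log(5), log(300))),
    distance_km = runif(n, 0, 8),
    start_time = runif(n, 0, 24),
    protocol = sample(c("stationary", "traveling"), n, TRUE),
    all_species_reported = TRUE, species = "spA",
    count = rpois(n, 4))
  m <- fit_effort_model(eff, "spA")
  ## each smooth explains essentially nothing
  expect_lt(summary(m$fit)$dev.expl, 0.02)
  res <- compute_residuals(m, eff)
  expect_lt(abs(mean(res$residual)), 0.02)
})

test_that("intercept-only limit: constant counts give fitted equal to the constant", {
  n <- 100
  eff <- data.frame(
    checklist_id = sprintf("c%04d", 1:n), cell_id = "g",
    observer_id = "o", date = "2021-06-01",
    duration_min = 60, distance_km = 1, start_time = 8,
    protocol = "traveling", all_species_reported = TRUE,
    species = "spA", count = 5)
  expect_warning(m <- fit_effort_model(eff, "spA"), "degenerate")
  res <- compute_residuals(m, eff)
  expect_equal(res$expected, rep(5, n), tolerance = 1e-6)
  expect_equal(res$residual, rep(0, n), tolerance = 1e-6)
})

test_that("counts rising with duration give larger fitted values at long durations", {
  set.seed(22)
  n <- 1000
  dur <- exp(runif(n, log(5), log(300)))
  eff <- data.frame(
    checklist_id = sprintf("c%04d", 1:n), cell_id = "g",
    observer_id = "o", date = "2021-06-01",
    duration_min = dur, distance_km = runif(n, 0, 5),
    start_time = runif(n, 5, 12), protocol = "traveling",
    all_species_reported = TRUE, species = "spA",
    count = rpois(n, exp(0.5 + 0.8 * (log(dur) - log(60)))))
  m <- suppressWarnings(fit_effort_model(eff, "spA"))
  d5 <- eff[1, ]; d5$duration_min <- 5
  d300 <- eff[1, ]; d300$duration_min <- 300
  lo <- compute_residuals(m, d5)
  hi <- compute_residuals(m, d300)
  expect_gt(hi$expected, lo$expected)
})

test_that("residuals follow the log1p closed form", {
  ## count 7 against expected 3: log(8) - log(4)
  expect_equal(log1p(7) - log1p(3), log(2))
  cfg <- small_config()
  cl <- filter_checklists(
    generate_bird_checklists(generate_landscape(cfg), cfg)$checklists)
  m <- fit_effort_model(cl, "bird_sp01", min_checklists = 10)
  res <- compute_residuals(m, cl)
  expect_equal(res$residual, log1p(res$count) - log1p(res$expected))
  ## zero count with zero expected is exactly zero
  expect_equal(log1p(0) - log1p(0), 0)
})

test_that("unseen protocol levels are rejected by name", {
  cfg <- small_config()
  cl <- filter_checklists(
    generate_bird_checklists(generate_landscape(cfg), cfg)$checklists)
  cl_tr <- cl[cl$protocol == "traveling", ]
  m <- suppressWarnings(fit_effort_model(cl_tr, "bird_sp01",
                                         min_checklists = 10))
  expect_error(compute_residuals(m, cl), "stationary")
})

test_that("cell mean residuals average correctly and ignore checklist order", {
  res <- data.frame(checklist_id = c("a", "b", "c"),
                    cell_id = c("g1", "g1", "g2"),
                    species = "spA", count = 1, expected = 1,
                    residual = c(0.5, -0.5, 0.25))
  cm <- cell_mean_residuals(res)
  expect_equal(cm$mean_residual[cm$cell_id == "g1"], 0)
  expect_equal(cm$mean_residual[cm$cell_id == "g2"], 0.25)
  cm2 <- cell_mean_residuals(res[c(3, 1, 2), ])
  expect_equal(cm[order(cm$cell_id), ], cm2[order(cm2$cell_id), ],
               ignore_attr = TRUE)
})

test_that("training residual means are near zero per species", {
  cfg <- synth_config(n_cells = 60, n_bird_species = 2,
                      checklists_per_cell_range = c(5L, 10L), seed = 4L)
  cl <- filter_checklists(
    generate_bird_checklists(generate_landscape(cfg), cfg)$checklists)
  for (sp in c("bird_sp01", "bird_sp02")) {
    m <- fit_effort_model(cl, sp)
    res <- compute_residuals(m, cl)
    expect_lt(abs(mean(res$residual)), 0.02)
  }
})

test_that("prevalence filter honors thresholds, whitelist and blocklist", {
  ## 100 cells; spLow detected in 19, spEdge in 20, spHigh in 60
  cells <- sprintf("g%03d", 1:100)
  mk <- function(sp, k) data.frame(checklist_id = paste0(sp, 1:k),
                                   cell_id = cells[1:k], species = sp,
                                   count = 1)
  cl <- rbind(mk("spLow", 19), mk("spEdge", 20), mk("spHigh", 60))
  cov <- c(spLow = 0.9, spEdge = 0.40, spHigh = 0.9)
  out <- species_prevalence_filter(cl, cells = cells, range_coverage = cov)
  expect_false(out$retained[out$species == "spLow"])
  expect_true(out$retained[out$species == "spEdge"])    # >= at both bounds
  expect_true(out$retained[out$species == "spHigh"])
  ## grassland-obligate style whitelist rescues a sub-threshold species
  out2 <- species_prevalence_filter(cl, cells = cells, range_coverage = cov,
                                    whitelist = "spLow")
  expect_true(out2$retained[out2$species == "spLow"])
  ## flyover blocklist removes regardless of prevalence
  out3 <- species_prevalence_filter(cl, cells = cells, range_coverage = cov,
                                    blocklist = "spHigh")
  expect_false(out3$retained[out3$species == "spHigh"])
  ## missing coverage counts as failing, with a logged reason
  out4 <- species_prevalence_filter(cl, cells = cells,
                                    range_coverage = cov[-3])
  expect_false(out4$retained[out4$species == "spHigh"])
  expect_equal(out4$reason[out4$species == "spHigh"], "coverage_missing")
})
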
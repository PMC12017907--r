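#' Filter bird checklists to the analysis set
#'
#' Retains complete checklists (all species reported with numeric counts)
#' within the breeding season window, using the stationary or traveling
#' protocol, lasting 5 to 300 minutes, from observers with at least
#' `min_observer_checklists` checklists in the dataset.
#'
#' @param checklists long data.frame, one row per checklist x species, with
#'   columns `checklist_id`, `cell_id`, `observer_id`, `date`,
#'   `duration_min`, `distance_km`, `start_time`, `protocol`, `species`,
#'   `count`, and optionally `all_species_reported`.
#' @param season character length-2 `"MM-DD"` bounds (inclusive), default
#'   May 15 to August 15.
#' @param duration_range retained duration interval in minutes.
#' @param min_observer_checklists minimum checklists per observer.
#' @return the retained rows of `checklists`.
#' @export
filter_checklists <- function(checklists,
                              season = c("05-15", "08-15"),
                              duration_range = c(5, 300),
                              min_observer_checklists = 3) {
  cl <- checklists
  cnt <- suppressWarnings(as.numeric(cl$count))
  ## checklists reporting any non-numeric count (e.g. presence-only "X")
  ## are not complete in the sense we need — drop the whole checklist
  bad_count <- unique(cl$checklist_id[is.na(cnt)])
  cl$count <- cnt
  keep <- !(cl$checklist_id %in% bad_count)
  if ("all_species_reported" %in% names(cl)) {
    keep <- keep & cl$all_species_reported %in% TRUE
  }
  mmdd <- format(as.Date(as.character(cl$date)), "%m-%d")
  keep <- keep & !is.na(mmdd) & mmdd >= season[1] & mmdd <= season[2]
  keep <- keep & cl$duration_min >= duration_range[1] &
    cl$duration_min <= duration_range[2]
  keep <- keep & cl$protocol %in% c("stationary", "traveling")
  cl <- cl[keep, , drop = FALSE]
  ## observer experience: count distinct checklists among those remaining
  per_obs <- tapply(cl$checklist_id, cl$observer_id,
                    function(x) length(unique(x)))
  ok_obs <- names(per_obs)[per_obs >= min_observer_checklists]
  cl <- cl[cl$observer_id %in% ok_obs, , drop = FALSE]
  rownames(cl) <- NULL
  cl
}

## One row per checklist for a single species, explicit zero counts
## (complete checklists imply absence = 0).
checklist_design <- function(checklists, species) {
  eff_cols <- c("checklist_id", "cell_id", "duration_min", "distance_km",
                "start_time", "protocol")
  eff <- unique(checklists[, eff_cols, drop = FALSE])
  if (anyDuplicated(eff$checklist_id)) {
    stop("inconsistent effort values within a checklist")
  }
  sp_rows <- checklists[checklists$species == species, ]
  eff$count <- sp_rows$count[match(eff$checklist_id, sp_rows$checklist_id)]
  eff$count[is.na(eff$count)] <- 0
  eff$protocol <- factor(eff$protocol)
  rownames(eff) <- NULL
  eff
}

#' Fit a per-species survey-effort model
#'
#' A generalized additive model of the species' count per checklist on
#' smooth terms for duration, distance traveled and start time plus a
#' protocol term.  The default fits `log(count + 1)` with Gaussian error,
#' making the log-scale residuals literal; `family = "poisson"` fits a
#' log-link count likelihood instead.  Smooths over covariates with too
#' little variation are dropped with a warning rather than failing.
#'
#' @param checklists filtered long checklist table.
#' @param species the species to model.
#' @param k basis dimension per smooth (small by default to guard
#'   overfitting).
#' @param family `"log1p_gaussian"` (default) or `"poisson"`.
#' @param min_checklists minimum number of checklists required.
#' @return an object of class `species_effort_model` wrapping the mgcv fit.
#' @export
fit_effort_model <- function(checklists, species, k = 5,
                             family = c("log1p_gaussian", "poisson"),
                             min_checklists = 50) {
  family <- match.arg(family)
  d <- checklist_design(checklists, species)
  if (nrow(d) < min_checklists) {
    stop("fewer than ", min_checklists, " checklists for ", species)
  }
  terms <- character(0)
  dropped <- character(0)
  for (v in c("duration_min", "distance_km", "start_time")) {
    if (length(unique(d[[v]])) > k) {
      terms <- c(terms, sprintf("s(%s, k = %d)", v, k))
    } else {
      dropped <- c(dropped, v)
    }
  }
  if (nlevels(d$protocol) > 1) {
    terms <- c(terms, "protocol")
  } else {
    dropped <- c(dropped, "protocol")
  }
  if (length(dropped)) {
    warning("dropped degenerate terms for ", species, ": ",
            paste(dropped, collapse = ", "))
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  if (family == "log1p_gaussian") {
    form <- stats::as.formula(paste("log1p(count) ~", rhs))
    fit <- mgcv::gam(form, data = d)
  } else {
    form <- stats::as.formula(paste("count ~", rhs))
    fit <- mgcv::gam(form, data = d, family = stats::poisson())
  }
  structure(list(species = species, fit = fit, family = family,
                 protocol_levels = levels(d$protocol),
                 dropped_terms = dropped),
            class = "species_effort_model")
}

#' @export
print.species_effort_model <- function(x, ...) {
  cat("Effort model for", x$species, "(", x$family, ")\n")
  cat("  deviance explained:",
      round(summary(x$fit)$dev.expl, 3), "\n")
  invisible(x)
}

## expected count on the natural scale for a design frame
predict_expected_count <- function(model, d) {
  mu <- as.vector(mgcv::predict.gam(model$fit, newdata = d,
                                    type = "response"))
  if (model$family == "log1p_gaussian") {
    mu <- expm1(pmax(mu, 0))   # back from the log1p scale, floored at 0
  }
  mu
}

#' Log-scale effort residuals per checklist
#'
#' `residual = log(count + 1) - log(expected + 1)`: positive where the
#' species was more abundant than expected for the checklist's effort.
#'
#' @param model a [fit_effort_model()] result.
#' @param checklists long checklist table covering the model's species.
#' @return data.frame `checklist_id`, `cell_id`, `species`, `count`,
#'   `expected`, `residual`.
#' @export
compute_residuals <- function(model, checklists) {
  d <- checklist_design(checklists, model$species)
  unseen <- setdiff(levels(d$protocol), model$protocol_levels)
  if (length(unseen)) {
    stop("protocol level not seen in training: ",
         paste(unseen, collapse = ", "))
  }
  d$protocol <- factor(as.character(d$protocol),
                       levels = model$protocol_levels)
  mu <- predict_expected_count(model, d)
  data.frame(checklist_id = d$checklist_id,
             cell_id = d$cell_id,
             species = model$species,
             count = d$count,
             expected = mu,
             residual = log1p(d$count) - log1p(mu))
}

#' Mean effort residual per grid cell and species
#'
#' @param residuals output of [compute_residuals()] (several species may be
#'   stacked).
#' @return data.frame `cell_id`, `species`, `mean_residual`, `n_checklists`.
#' @export
cell_mean_residuals <- function(residuals) {
  out <- agg_by(residuals, c("cell_id", "species"), function(d) {
    data.frame(mean_residual = mean(d$residual),
               n_checklists = nrow(d))
  }, c("mean_residual", "n_checklists"))
  rownames(out) <- NULL
  out
}

#' Prevalence and range-coverage filter for candidate bird species
#'
#' Retains species detected in at least `min_cell_prevalence` of the grid
#' cells and whose breeding range covers at least `min_range_coverage` of
#' the study area, both inclusive.  Whitelisted species (e.g. grassland
#' obligates of particular interest) are kept even slightly below the
#' prevalence threshold; blocklisted species (e.g. flyover-detected
#' raptors and aerial feeders) are always removed.  Species missing from
#' `range_coverage` are treated as failing and logged.
#'
#' @param checklists filtered long checklist table (counts with zeros or
#'   detections only — prevalence uses counts > 0).
#' @param cells optional character vector of the cell universe; defaults to
#'   the cells present in `checklists`.
#' @param min_cell_prevalence minimum fraction of cells with a detection.
#' @param range_coverage named numeric, species -> fraction of study area
#'   covered by its breeding range.  `NULL` skips the coverage test.
#' @param min_range_coverage minimum coverage fraction.
#' @param whitelist,blocklist species name vectors.
#' @return data.frame `species`, `prevalence`, `range_coverage`,
#'   `retained`, `reason`.
#' @export
species_prevalence_filter <- function(checklists, cells = NULL,
                                      min_cell_prevalence = 0.20,
                                      range_coverage = NULL,
                                      min_range_coverage = 0.40,
                                      whitelist = character(),
                                      blocklist = character()) {
  cells <- cells %||% unique(checklists$cell_id)
  det <- checklists[checklists$count > 0, c("cell_id", "species")]
  det <- unique(det)
  prev <- tapply(det$cell_id, det$species,
                 function(x) length(unique(x)) / length(cells))
  species <- sort(unique(as.character(checklists$species)))
  prevalence <- ifelse(species %in% names(prev), prev[species], 0)
  cov <- if (is.null(range_coverage)) {
    rep(NA_real_, length(species))
  } else {
    unname(range_coverage[species])
  }
  retained <- logical(length(species))
  reason <- character(length(species))
  for (i in seq_along(species)) {
    s <- species[i]
    if (s %in% blocklist) {
      reason[i] <- "blocklist"
    } else if (s %in% whitelist) {
      retained[i] <- TRUE
      reason[i] <- "whitelist"
    } else if (prevalence[i] < min_cell_prevalence) {
      reason[i] <- "prevalence"
    } else if (!is.null(range_coverage) &&
               (is.na(cov[i]) || cov[i] < min_range_coverage)) {
      reason[i] <- if (is.na(cov[i])) "coverage_missing" else "coverage"
    } else {
      retained[i] <- TRUE
      reason[i] <- "ok"
    }
  }
  data.frame(species = species, prevalence = as.numeric(prevalence),
             range_coverage = cov, retained = retained, reason = reason)
}

#' Per-cell bird features for a set of species
#'
#' Convenience wrapper: fits the effort model and computes cell mean
#' residuals for each species, returning the stacked long feature table.
#'
#' @param checklists filtered long checklist table.
#' @param species character vector of species to model.
#' @param ... passed to [fit_effort_model()].
#' @return data.frame `cell_id`, `species`, `mean_residual`, `n_checklists`.
#' @export
bird_cell_features <- function(checklists, species, ...) {
  res <- lapply(species, function(s) {
    m <- fit_effort_model(checklists, s, ...)
    compute_residuals(m, checklists)
  })
  cell_mean_residuals(do.call(rbind, res))
}
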
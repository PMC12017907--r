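#' Configuration for the synthetic bee-bird-landscape generator
#'
#' Bundles every knob of the synthetic study system: a square-ish grid of
#' 3x3 km cells with compositional land cover, bird populations whose
#' checklist counts are confounded by survey effort, and bee surveys whose
#' per-cell standardized richness is a sparse linear function of scaled
#' predictors plus Gaussian noise.
#'
#' The generated feature set is the union of land-cover percentages
#' (`lc01`, `lc02`, ...) and per-species bird log-densities
#' (`bird_sp01`, ...).  `n_true_predictors` of these carry the signal; the
#' rest are decoys.  True predictors alternate between land-cover and bird
#' columns so both data kinds contribute.
#'
#' @param n_cells number of grid cells.
#' @param n_landcover_classes number of land-cover classes (>= 2).
#' @param n_bird_species number of bird species.
#' @param n_true_predictors how many predictors carry non-zero coefficients.
#' @param true_coefficients coefficients of the true predictors, in units of
#'   response SD per predictor SD. Recycled default alternates sign with
#'   magnitudes in \[0.3, 0.5\].
#' @param noise_sd SD of the cell-level Gaussian noise on the latent
#'   richness. `NULL` (default) matches it to the SD of the realized linear
#'   predictor, giving a theoretical R-squared of 0.5 — an intermediate
#'   signal-to-noise typical of landscape-scale richness models.
#' @param intercept latent mean richness (species per survey).
#' @param surveys_per_cell_range integer interval for bee surveys per cell.
#' @param checklists_per_cell_range integer interval for bird checklists per
#'   cell.
#' @param effort_effects named logicals switching each effort confounder on:
#'   `duration`, `distance`, `start_time`, `protocol`.
#' @param landcover_concentration Dirichlet concentration; smaller values
#'   give patchier (more uneven) cell compositions.
#' @param bird_density_sd SD of cell-to-cell variation in species
#'   log-density.
#' @param overdispersion `NULL` for Poisson bird counts, or a positive
#'   negative-binomial size parameter for overdispersed counts.
#' @param seed integer seed; all generator stages derive their own seeds
#'   from it by fixed offsets.
#'
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_cells = 500L,
                         n_landcover_classes = 8L,
                         n_bird_species = 12L,
                         n_true_predictors = 5L,
                         true_coefficients = NULL,
                         noise_sd = NULL,
                         intercept = 5,
                         surveys_per_cell_range = c(2L, 6L),
                         checklists_per_cell_range = c(5L, 15L),
                         effort_effects = c(duration = TRUE, distance = TRUE,
                                            start_time = TRUE, protocol = TRUE),
                         landcover_concentration = 1.5,
                         bird_density_sd = 0.8,
                         overdispersion = NULL,
                         seed = 1L) {
  if (n_landcover_classes < 2) stop("n_landcover_classes must be >= 2")
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (n_true_predictors > n_landcover_classes + n_bird_species) {
    stop("n_true_predictors exceeds the number of candidate predictors")
  }
  if (is.null(true_coefficients)) {
    mags <- rep(c(0.5, -0.4, 0.4, -0.35, 0.3), length.out = n_true_predictors)
    true_coefficients <- mags
  }
  if (length(true_coefficients) != n_true_predictors) {
    stop("true_coefficients must have length n_true_predictors")
  }
  if (!is.null(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0")
  chk_range <- function(r, nm) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < 1) {
      stop(nm, " must be an integer interval with 1 <= low <= high")
    }
    as.integer(r)
  }
  surveys_per_cell_range <- chk_range(surveys_per_cell_range,
                                      "surveys_per_cell_range")
  checklists_per_cell_range <- chk_range(checklists_per_cell_range,
                                         "checklists_per_cell_range")
  flags <- c(duration = TRUE, distance = TRUE, start_time = TRUE,
             protocol = TRUE)
  flags[names(effort_effects)] <- effort_effects
  structure(list(
    n_cells = as.integer(n_cells),
    n_landcover_classes = as.integer(n_landcover_classes),
    n_bird_species = as.integer(n_bird_species),
    n_true_predictors = as.integer(n_true_predictors),
    true_coefficients = true_coefficients,
    noise_sd = noise_sd,
    intercept = intercept,
    surveys_per_cell_range = surveys_per_cell_range,
    checklists_per_cell_range = checklists_per_cell_range,
    effort_effects = flags,
    landcover_concentration = landcover_concentration,
    bird_density_sd = bird_density_sd,
    overdispersion = overdispersion,
    seed = as.integer(seed)
  ), class = "synth_config")
}

landcover_names <- function(config) {
  sprintf("lc%02d", seq_len(config$n_landcover_classes))
}

bird_names <- function(config) {
  sprintf("bird_sp%02d", seq_len(config$n_bird_species))
}

#' Generate a synthetic landscape of compositional land cover
#'
#' Cells sit on a square grid with 3 km spacing (planar x/y in km).  Each
#' cell's land-cover percentages are a draw from a symmetric Dirichlet
#' distribution scaled to 100, so rows are nonnegative and close to 100
#' exactly.
#'
#' @param config a [synth_config()].
#' @return data.frame with `cell_id`, `x`, `y` (cell lower-left corner, km)
#'   and one percentage column per land-cover class.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(stage_seed(config$seed, "landscape"), {
    n <- config$n_cells
    k <- config$n_landcover_classes
    nx <- ceiling(sqrt(n))
    ix <- (seq_len(n) - 1L) %% nx
    iy <- (seq_len(n) - 1L) %/% nx
    g <- matrix(stats::rgamma(n * k, shape = config$landcover_concentration),
                nrow = n)
    pct <- 100 * g / rowSums(g)
    colnames(pct) <- landcover_names(config)
    out <- data.frame(cell_id = sprintf("cell_%04d", seq_len(n)),
                      x = ix * 3, y = iy * 3)
    cbind(out, as.data.frame(pct))
  })
}

## Smooth effort effects on the log-count scale.  Centered so that a
## "typical" checklist (60 min, 1 km, 08:00, traveling) has offset ~ 0.
effort_offset <- function(duration, distance, start_time, protocol, flags,
                          duration_slope = 0.8) {
  off <- numeric(length(duration))
  if (flags[["duration"]]) off <- off + duration_slope * (log(duration) - log(60))
  if (flags[["distance"]]) off <- off + 0.25 * (sqrt(distance) - 1)
  if (flags[["start_time"]]) off <- off - 0.01 * (start_time - 8)^2
  if (flags[["protocol"]]) off <- off - 0.3 * (protocol == "stationary")
  off
}

#' Generate synthetic bird checklists with effort confounding
#'
#' Each cell receives a number of complete checklists drawn uniformly from
#' the configured interval.  Per-species expected counts follow a log link:
#' species log-density in the cell plus smooth effects of duration, distance
#' and start time and a protocol offset (each switchable via
#' `config$effort_effects`).  Counts are Poisson by default, negative
#' binomial when `config$overdispersion` is set.
#'
#' @param landscape output of [generate_landscape()].
#' @param config a [synth_config()].
#' @return list with `checklists` (long data.frame, one row per checklist x
#'   species, zero counts included) and `truth` (per-cell per-species true
#'   log-density matrix plus the effort-effect settings).
#' @export
generate_bird_checklists <- function(landscape, config) {
  stopifnot(inherits(config, "synth_config"))
  if (nrow(landscape) == 0) stop("landscape has no cells")
  lo <- config$checklists_per_cell_range[1]
  hi <- config$checklists_per_cell_range[2]
  if (hi < 1) stop("zero checklists requested")
  with_seed(stage_seed(config$seed, "birds"), {
    n <- nrow(landscape)
    sp <- bird_names(config)
    ## species base abundance + cell-level variation on the log scale
    base <- stats::runif(length(sp), log(0.5), log(6))
    dens <- outer(rep(0, n), base, `+`) +
      matrix(stats::rnorm(n * length(sp), 0, config$bird_density_sd), nrow = n)
    dimnames(dens) <- list(landscape$cell_id, sp)

    n_cl <- lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
    cell_idx <- rep(seq_len(n), n_cl)
    m <- length(cell_idx)
    observers <- sprintf("obs%03d", sample(max(2L, n %/% 2L), m, replace = TRUE))
    duration <- round(exp(stats::runif(m, log(5), log(300))), 1)
    protocol <- ifelse(stats::runif(m) < 0.3, "stationary", "traveling")
    distance <- ifelse(protocol == "stationary", 0,
                       round(stats::runif(m, 0.2, 8), 2))
    start_time <- round(pmin(pmax(stats::rnorm(m, 9, 3), 0), 23.9), 2)
    date <- as.Date("2021-05-15") + sample(0:91, m, replace = TRUE)
    off <- effort_offset(duration, distance, start_time, protocol,
                         config$effort_effects)

    lambda <- exp(dens[cell_idx, , drop = FALSE] + off)
    if (is.null(config$overdispersion)) {
      counts <- matrix(stats::rpois(m * length(sp), lambda), nrow = m)
    } else {
      counts <- matrix(stats::rnbinom(m * length(sp),
                                      mu = lambda,
                                      size = config$overdispersion), nrow = m)
    }
    checklists <- data.frame(
      checklist_id = rep(sprintf("cl%06d", seq_len(m)), times = length(sp)),
      cell_id = rep(landscape$cell_id[cell_idx], times = length(sp)),
      observer_id = rep(observers, times = length(sp)),
      date = rep(date, times = length(sp)),
      duration_min = rep(duration, times = length(sp)),
      distance_km = rep(distance, times = length(sp)),
      start_time = rep(start_time, times = length(sp)),
      protocol = rep(protocol, times = length(sp)),
      all_species_reported = TRUE,
      species = rep(sp, each = m),
      count = as.integer(counts)
    )
    list(checklists = checklists,
         truth = list(log_density = dens,
                      effort_effects = config$effort_effects))
  })
}

## The candidate predictor table the bee response is built from: land-cover
## percentages joined with true bird log-densities, z-scored across cells.
synth_feature_table <- function(landscape, bird_truth, config) {
  lc <- as.matrix(landscape[, landcover_names(config), drop = FALSE])
  X <- cbind(lc, bird_truth$log_density)
  Xs <- scale(X)
  attr(Xs, "scaled:center") <- NULL
  attr(Xs, "scaled:scale") <- NULL
  rownames(Xs) <- landscape$cell_id
  Xs
}

true_predictor_names <- function(config) {
  lc <- landcover_names(config)
  bd <- bird_names(config)
  ## alternate land-cover and bird columns until the quota is filled
  picks <- character(0)
  i_lc <- 1L; i_bd <- 1L
  for (j in seq_len(config$n_true_predictors)) {
    if (j %% 2 == 1 && i_lc <= length(lc)) {
      picks <- c(picks, lc[i_lc]); i_lc <- i_lc + 1L
    } else if (i_bd <= length(bd)) {
      picks <- c(picks, bd[i_bd]); i_bd <- i_bd + 1L
    } else {
      picks <- c(picks, lc[i_lc]); i_lc <- i_lc + 1L
    }
  }
  picks
}

#' Generate synthetic bee surveys with a known richness signal
#'
#' The latent standardized richness of each cell is
#' `intercept + sum(beta * scaled predictor) + Normal(0, noise_sd)`, with
#' the scaled predictors drawn from the landscape's land-cover percentages
#' and the true bird log-densities.  Two realization modes:
#'
#' * `"direct"` — the per-cell response is emitted as-is, with no
#'   survey-level sampling; separates estimator error from sampling error.
#' * `"surveys"` — each cell receives surveys; each survey records a number
#'   of distinct species that is Poisson around the latent richness
#'   (`sampling = "poisson"`) or its rounded value (`sampling = "exact"`),
#'   emitted as one occurrence record per species per survey in the same
#'   CSV dialect the ingestion functions read.
#'
#' @param landscape output of [generate_landscape()].
#' @param bird_truth the `truth` element of [generate_bird_checklists()].
#' @param config a [synth_config()].
#' @param mode `"direct"` or `"surveys"`.
#' @param sampling species-count realization within surveys.
#' @return list with `records` (NULL in direct mode), `cell_richness`
#'   (direct-mode response table), and `truth`: cell ids, the scaled feature
#'   matrix, the named true coefficient map, the latent linear predictor,
#'   the realized response, `noise_sd` and the theoretical R-squared
#'   `var(lp) / (var(lp) + noise_sd^2)`.
#' @export
generate_bee_surveys <- function(landscape, bird_truth, config,
                                 mode = c("direct", "surveys"),
                                 sampling = c("poisson", "exact")) {
  stopifnot(inherits(config, "synth_config"))
  mode <- match.arg(mode)
  sampling <- match.arg(sampling)
  X <- synth_feature_table(landscape, bird_truth, config)
  truth_names <- true_predictor_names(config)
  if (!all(truth_names %in% colnames(X))) {
    stop("true predictors missing from the generated feature set: ",
         paste(setdiff(truth_names, colnames(X)), collapse = ", "))
  }
  beta <- stats::setNames(config$true_coefficients, truth_names)
  lp <- config$intercept + as.vector(X[, truth_names, drop = FALSE] %*% beta)
  noise_sd <- config$noise_sd %||% stats::sd(lp)
  with_seed(stage_seed(config$seed, "bees"), {
    latent <- lp + stats::rnorm(length(lp), 0, noise_sd)
    truth <- list(
      cell_id = landscape$cell_id,
      features = X,
      coefficients = beta,
      linear_predictor = lp,
      response = latent,
      noise_sd = noise_sd,
      theoretical_r2 = stats::var(lp) / (stats::var(lp) + noise_sd^2)
    )
    cell_richness <- data.frame(cell_id = landscape$cell_id,
                                richness = latent,
                                n_surveys = NA_integer_,
                                n_records = NA_integer_,
                                mode = "direct")
    if (mode == "direct") {
      return(list(records = NULL, cell_richness = cell_richness,
                  truth = truth))
    }
    ## survey mode: realize species lists per survey
    pool <- sprintf("Bee_species_%03d", seq_len(150))
    lo <- config$surveys_per_cell_range[1]
    hi <- config$surveys_per_cell_range[2]
    n_surv <- lo + sample.int(hi - lo + 1L, nrow(landscape),
                              replace = TRUE) - 1L
    recs <- vector("list", sum(n_surv))
    r <- 0L
    for (i in seq_len(nrow(landscape))) {
      mu <- max(latent[i], 0)
      for (s in seq_len(n_surv[i])) {
        k <- if (sampling == "exact") max(round(mu), 0) else stats::rpois(1, mu)
        r <- r + 1L
        if (k == 0) next
        spp <- sample(pool, min(k, length(pool)))
        recs[[r]] <- data.frame(
          species = spp,
          latitude = landscape$y[i] + stats::runif(1, 0, 3),
          longitude = landscape$x[i] + stats::runif(1, 0, 3),
          date = as.character(as.Date("2021-05-01") +
                                sample(0:120, 1)),
          coord_uncertainty_km = round(stats::runif(1, 0, 1.5), 3),
          survey_id = sprintf("srv_%04d_%02d", i, s),
          trap_id = NA_character_
        )
      }
    }
    records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
    rownames(records) <- NULL
    list(records = records, cell_richness = cell_richness, truth = truth)
  })
}

#' Write a synthetic dataset to disk in the pipeline's input dialects
#'
#' Emits the bee records CSV, the checklist TSV, the land-cover CSV and the
#' ground truth (CSV for per-cell values, JSON for the coefficient map).
#'
#' @param dir output directory, created if needed.
#' @param config a [synth_config()].
#' @param mode passed to [generate_bee_surveys()].
#' @return invisibly, the list of generated objects.
#' @export
write_synthetic_dataset <- function(dir, config, mode = "surveys") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  land <- generate_landscape(config)
  birds <- generate_bird_checklists(land, config)
  bees <- generate_bee_surveys(land, birds$truth, config, mode = mode)
  utils::write.csv(land, file.path(dir, "landcover.csv"), row.names = FALSE)
  utils::write.table(birds$checklists, file.path(dir, "checklists.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(bees$records)) {
    utils::write.csv(bees$records, file.path(dir, "bee_records.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(
    data.frame(cell_id = bees$truth$cell_id,
               linear_predictor = bees$truth$linear_predictor,
               response = bees$truth$response),
    file.path(dir, "ground_truth_cells.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(bees$truth$coefficients),
                       file.path(dir, "ground_truth_coefficients.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(landscape = land, birds = birds, bees = bees))
}
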
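#' Grid specification for 3x3 km cell assignment
#'
#' Cells are half-open squares `[x0 + i*s, x0 + (i+1)*s)` on both axes, in
#' the planar units of the record coordinates (km for the synthetic
#' generators; project real coordinates to an equal-area system first —
#' a "3 km" cell is a metric statement).
#'
#' @param origin numeric length-2, lower-left corner `(x0, y0)`.
#' @param cell_size_km cell edge length.
#' @param nx,ny optional extent in cells; records falling outside
#'   `[0, nx)` x `[0, ny)` cell indices are excluded as out of extent.
#'   `NULL` leaves the axis unbounded.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(origin = c(0, 0), cell_size_km = 3,
                      nx = NULL, ny = NULL) {
  stopifnot(length(origin) == 2, cell_size_km > 0)
  structure(list(origin = as.numeric(origin),
                 cell_size_km = as.numeric(cell_size_km),
                 nx = nx, ny = ny),
            class = "grid_spec")
}

#' Filter bee occurrence records
#'
#' Applies the record-level exclusion rules: unparseable or missing
#' coordinates/date, missing species identification, coordinate uncertainty
#' above `max_uncertainty_km`, exact duplicates, and (optionally) a year
#' window.  Structured mode additionally drops whole surveys in which fewer
#' than `min_identified_fraction` of specimens carry a species
#' identification, and honeybee records (a configurable blocklist applied
#' in both modes by default).  Every dropped record appears in the
#' exclusion log with exactly one reason, so retained + excluded always
#' partition the input.
#'
#' @param records data.frame with columns `species`, `latitude`,
#'   `longitude`, `date`, and optionally `coord_uncertainty_km`,
#'   `survey_id`, `trap_id`.
#' @param mode `"semi_structured"` or `"structured"`.
#' @param max_uncertainty_km records with larger geographic uncertainty are
#'   excluded (default 3 km, the grid cell size).
#' @param year_window optional integer vector of years to retain.
#' @param min_identified_fraction structured mode: minimum fraction of a
#'   survey's specimens identified to species.
#' @param honeybee_blocklist species names always excluded.
#' @return list with `records` (retained, plus a parsed `date` column) and
#'   `exclusions` (data.frame `row`, `reason`).
#' @export
filter_records <- function(records,
                           mode = c("semi_structured", "structured"),
                           max_uncertainty_km = 3,
                           year_window = NULL,
                           min_identified_fraction = 0.90,
                           honeybee_blocklist = "Apis mellifera") {
  mode <- match.arg(mode)
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  if (n == 0) {
    return(list(records = records,
                exclusions = data.frame(row = integer(0),
                                        reason = character(0))))
  }
  mark <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    reason[is.na(reason) & bad] <<- why
  }

  lat <- suppressWarnings(as.numeric(records$latitude))
  lon <- suppressWarnings(as.numeric(records$longitude))
  ## ISO dates only; anything else becomes NA and is excluded, not fatal
  dt <- as.Date(as.character(records$date), format = "%Y-%m-%d")
  mark(is.na(lat) | is.na(lon) | !is.finite(lat) | !is.finite(lon),
       "missing_location")
  mark(is.na(dt), "missing_date")
  sp <- as.character(records$species)
  mark(is.na(sp) | !nzchar(trimws(sp)), "missing_species")

  unc <- if ("coord_uncertainty_km" %in% names(records)) {
    suppressWarnings(as.numeric(records$coord_uncertainty_km))
  } else rep(NA_real_, n)
  mark(!is.na(unc) & unc > max_uncertainty_km, "uncertainty")

  if (!is.null(year_window)) {
    yr <- as.integer(format(dt, "%Y"))
    mark(!is.na(dt) & !(yr %in% year_window), "year_window")
  }

  mark(sp %in% honeybee_blocklist, "honeybee")

  ## duplicates: identical (species, lat, lon, date, survey_id), first kept
  sid <- if ("survey_id" %in% names(records)) {
    as.character(records$survey_id)
  } else rep(NA_character_, n)
  key <- paste(sp, lat, lon, as.character(dt), sid, sep = "\r")
  mark(is.na(reason) & duplicated(key), "duplicate")

  if (mode == "structured") {
    ## identification fraction per survey, computed on the raw input so
    ## unidentified specimens count toward the denominator
    skey <- if (any(!is.na(sid))) sid else paste(lat, lon, as.character(dt))
    identified <- !(is.na(sp) | !nzchar(trimws(sp)))
    frac <- tapply(identified, skey, mean)
    bad_surveys <- names(frac)[frac < min_identified_fraction]
    mark(skey %in% bad_surveys & is.na(reason), "survey_identification")
  }

  keep <- is.na(reason)
  out <- records[keep, , drop = FALSE]
  out$latitude <- lat[keep]
  out$longitude <- lon[keep]
  out$date <- dt[keep]
  rownames(out) <- NULL
  list(records = out,
       exclusions = data.frame(row = which(!keep),
                               reason = reason[!keep]))
}

#' Assign records to grid cells
#'
#' Maps each record to the half-open cell containing its planar
#' coordinates (`longitude` as x, `latitude` as y).  A point exactly on a
#' shared edge belongs to the upper/right cell.
#'
#' @param records filtered records with numeric coordinates.
#' @param grid a [grid_spec()].
#' @return list with `records` (a `cell_id` column added) and `exclusions`
#'   for records outside a bounded extent (reason `"out_of_extent"`).
#' @export
assign_to_grid <- function(records, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  s <- grid$cell_size_km
  ix <- floor((records$longitude - grid$origin[1]) / s)
  iy <- floor((records$latitude - grid$origin[2]) / s)
  bad <- rep(FALSE, nrow(records))
  if (!is.null(grid$nx)) bad <- bad | ix < 0 | ix >= grid$nx
  if (!is.null(grid$ny)) bad <- bad | iy < 0 | iy >= grid$ny
  out <- records[!bad, , drop = FALSE]
  out$cell_id <- sprintf("g%d_%d", ix[!bad], iy[!bad])
  rownames(out) <- NULL
  list(records = out,
       exclusions = data.frame(row = which(bad),
                               reason = rep("out_of_extent", sum(bad))))
}

#' Standardized bee richness per grid cell
#'
#' Semi-structured mode: a survey is a unique (latitude, longitude, date)
#' combination; surveys with a single bee record are dropped; cells with
#' only one remaining survey and fewer than `min_cell_records` total
#' records are excluded; richness is the mean number of distinct species
#' per survey.  Structured mode: a survey is `survey_id`; richness is the
#' mean over surveys of the mean number of distinct species per trap
#' within the survey.
#'
#' @param records records carrying `cell_id` (see [assign_to_grid()]).
#' @param mode `"semi_structured"` or `"structured"`.
#' @param min_cell_records retention threshold for single-survey cells.
#' @return data.frame with `cell_id`, `richness`, `n_surveys`, `n_records`,
#'   `mode` — one row per retained cell.
#' @export
standardize_richness <- function(records,
                                 mode = c("semi_structured", "structured"),
                                 min_cell_records = 30) {
  mode <- match.arg(mode)
  if (!"cell_id" %in% names(records)) stop("records must carry cell_id")
  if (nrow(records) == 0) {
    return(data.frame(cell_id = character(0), richness = numeric(0),
                      n_surveys = integer(0), n_records = integer(0),
                      mode = character(0)))
  }
  if (mode == "semi_structured") {
    survey <- paste(records$latitude, records$longitude,
                    as.character(records$date), sep = "\r")
    per_survey <- agg_by(
      cbind(records, .survey = survey), c("cell_id", ".survey"),
      function(d) data.frame(n_species = length(unique(d$species)),
                             n_records = nrow(d)),
      c("n_species", "n_records"))
    per_survey <- per_survey[per_survey$n_records > 1, , drop = FALSE]
    if (nrow(per_survey) == 0) {
      return(standardize_richness(records[0, , drop = FALSE], mode))
    }
    cells <- agg_by(per_survey, "cell_id", function(d) {
      data.frame(richness = mean(d$n_species),
                 n_surveys = nrow(d),
                 n_records = sum(d$n_records))
    }, c("richness", "n_surveys", "n_records"))
    keep <- !(cells$n_surveys == 1 & cells$n_records < min_cell_records)
    cells <- cells[keep, , drop = FALSE]
  } else {
    if (!"survey_id" %in% names(records)) {
      stop("structured mode requires survey_id")
    }
    trap <- if ("trap_id" %in% names(records)) {
      ifelse(is.na(records$trap_id), "trap0", as.character(records$trap_id))
    } else rep("trap0", nrow(records))
    per_trap <- agg_by(
      cbind(records, .trap = trap), c("cell_id", "survey_id", ".trap"),
      function(d) data.frame(n_species = length(unique(d$species)),
                             n_records = nrow(d)),
      c("n_species", "n_records"))
    per_survey <- agg_by(per_trap, c("cell_id", "survey_id"), function(d) {
      data.frame(spp_per_trap = mean(d$n_species),
                 n_records = sum(d$n_records))
    }, c("spp_per_trap", "n_records"))
    cells <- agg_by(per_survey, "cell_id", function(d) {
      data.frame(richness = mean(d$spp_per_trap),
                 n_surveys = nrow(d),
                 n_records = sum(d$n_records))
    }, c("richness", "n_surveys", "n_records"))
  }
  rownames(cells) <- NULL
  data.frame(cell_id = as.character(cells$cell_id),
             richness = as.numeric(cells$richness),
             n_surveys = as.integer(cells$n_surveys),
             n_records = as.integer(cells$n_records),
             mode = rep(mode, nrow(cells)))
}
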
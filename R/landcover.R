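#' Aggregate raw land-cover classes to bee-relevant categories
#'
#' Takes per-cell pixel tallies of raw raster classes (e.g. the 30 m
#' crop-specific classes) and a many-to-one class-aggregation map, and
#' returns per-cell percentages of each aggregated category.
#'
#' @param class_counts data.frame `cell_id`, `class_code`, `n_pixels`.
#' @param aggregation_map data.frame `class_code`, `category`; every raw
#'   code present in `class_counts` must map to exactly one category.
#' @return data.frame with `cell_id` and one percentage column per
#'   category; each row sums to 100.
#' @export
aggregate_classes <- function(class_counts, aggregation_map) {
  if (anyDuplicated(aggregation_map$class_code)) {
    stop("aggregation map assigns some class codes more than once")
  }
  idx <- match(class_counts$class_code, aggregation_map$class_code)
  if (anyNA(idx)) {
    stop("unmapped class codes: ",
         paste(sort(unique(class_counts$class_code[is.na(idx)])),
               collapse = ", "))
  }
  cat_ <- as.character(aggregation_map$category[idx])
  cells <- sort(unique(as.character(class_counts$cell_id)))
  cats <- sort(unique(as.character(aggregation_map$category)))
  tot <- tapply(class_counts$n_pixels, class_counts$cell_id, sum)
  m <- matrix(0, nrow = length(cells), ncol = length(cats),
              dimnames = list(cells, cats))
  agg <- tapply(class_counts$n_pixels,
                list(as.character(class_counts$cell_id), cat_), sum)
  agg[is.na(agg)] <- 0
  m[rownames(agg), colnames(agg)] <- agg
  pct <- 100 * m / as.numeric(tot[cells])
  out <- data.frame(cell_id = cells, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(pct))
}

#' Prevalence filter for land-cover categories
#'
#' Retains categories present (percentage above `presence_threshold`) in at
#' least `min_prevalence` of the cells, inclusive.
#'
#' @param cell_landcover data.frame from [aggregate_classes()] (or any
#'   `cell_id` + percentage-column table).
#' @param min_prevalence minimum fraction of cells with presence.
#' @param presence_threshold percentage above which a category counts as
#'   present in a cell (default 0: any nonzero cover).
#' @return data.frame `category`, `prevalence`, `retained`.
#' @export
landcover_prevalence_filter <- function(cell_landcover,
                                        min_prevalence = 0.20,
                                        presence_threshold = 0) {
  cats <- setdiff(names(cell_landcover), c("cell_id", "x", "y"))
  prev <- vapply(cats, function(cc) {
    mean(cell_landcover[[cc]] > presence_threshold)
  }, numeric(1))
  data.frame(category = cats, prevalence = unname(prev),
             retained = unname(prev >= min_prevalence))
}
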
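#' @keywords internal
"_PACKAGE"

## Run `expr` under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Stage seeds derived from a single global seed by fixed offsets, so each
## generator stage is reproducible on its own.  Kept below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(landscape = 0L, birds = 101L, bees = 211L, folds = 307L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

## group-wise aggregate returning a plain data.frame with stable ordering
agg_by <- function(df, by, fun, ...) {
  keys <- interaction(df[by], drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(df)), keys)
  out_keys <- df[match(names(idx), as.character(keys)), by, drop = FALSE]
  vals <- lapply(idx, function(i) fun(df[i, , drop = FALSE]))
  out <- cbind(out_keys, do.call(rbind, vals))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
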
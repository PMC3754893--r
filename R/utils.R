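# shared internal helpers

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards. seed = NULL means "use the ambient RNG stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from a global seed; keeps results
# independent of stage order while staying below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}

stop_field <- function(field, why) {
  stop(sprintf("invalid `%s`: %s", field, why), call. = FALSE)
}

check_columns <- function(df, required, what = "table") {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

# median that returns NA (not NaN / error) on empty input
median_or_na <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  stats::median(x)
}
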
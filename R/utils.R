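# internal helpers shared across modules

stop_lan <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# required columns must all be present; error names the missing ones
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_lan("%s is missing required column(s): %s", what,
             paste(missing, collapse = ", "))
  }
  invisible(df)
}

check_probability <- function(p, what = "p") {
  if (!is.numeric(p)) stop_lan("%s must be numeric", what)
  bad <- which(!is.na(p) & (p < 0 | p > 1))
  if (length(bad) > 0) {
    stop_lan("%s contains value(s) outside [0, 1] at position(s) %s",
             what, paste(head(bad, 5), collapse = ", "))
  }
  invisible(p)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`, then restore
# the caller's RNG so generators are pure functions of their config
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
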
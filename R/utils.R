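# internal helpers

LAYERS <- c("protein", "phospho", "mrna")

# Run `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards. seed = NULL leaves the global stream
# untouched (results then depend on the ambient RNG state).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

match_layer <- function(layer) match.arg(layer, LAYERS)
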
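# internal helpers shared across modules

# Evaluate expr with a temporary RNG state seeded at `seed`; the caller's
# RNG stream is untouched (same contract as stats::simulate).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single number", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf,
                             lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  ok <- if (lo_open) x > lo else x >= lo
  ok <- ok && (if (hi_open) x < hi else x <= hi)
  if (!ok)
    stop(sprintf("'%s' = %g is outside its allowed range", name, x),
         call. = FALSE)
  invisible(x)
}

# sum of overlap between [s1, e1) and [s2, e2)
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}
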
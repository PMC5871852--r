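# internal helpers

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG
# state afterwards so generators never leak global state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
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

# geometric mean; zero present -> 0 (prod^(1/n) semantics)
geomean <- function(x) {
  if (any(x < 0)) stop("geometric mean requires non-negative values")
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

# population (divisor-N) standard deviation
popSd <- function(x) sqrt(mean((x - mean(x))^2))
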
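# Small internal helpers.

# Population variance (divisor n), used throughout: the z-score normalizer is
# defined with the overall standard deviation, and synthetic band components
# are rescaled to an exact realized variance.
var_pop <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

sd_pop <- function(x) sqrt(var_pop(x))

# Evaluate with a locally-seeded RNG without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed below 2^31.
child_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + as.numeric(i) * 1117) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a
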
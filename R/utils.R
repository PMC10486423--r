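# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's random stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

stop_ecgwo <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ecgwo("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stop_ecgwo("'%s' must be in [%s, %s], got %s", name,
               format(lower), format(upper), format(x))
  if (integer && x != round(x))
    stop_ecgwo("'%s' must be an integer, got %s", name, format(x))
  invisible(x)
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
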
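# Canonical continuous grey wolf optimizer.  A pack of candidate solutions
# is guided by its three best members (alpha, beta, delta); the remaining
# omega wolves move toward a stochastic average of the three leaders, with
# an exploration/exploitation balance set by a control scalar `a` that
# decays linearly to zero over the run.

#' Grey wolf optimizer configuration
#'
#' @param n_wolves pack size; at least 4 (three leaders plus at least one
#'   omega wolf).
#' @param n_iterations number of position-update iterations `T`.
#' @param bounds per-dimension search box: either a length-2 numeric
#'   `c(lower, upper)` recycled over all dimensions, or a `dim x 2` matrix.
#' @param seed integer seed; every run is bit-reproducible given the seed.
#' @param a_initial starting value of the control scalar `a`, which decays
#'   linearly as `a = a_initial * (1 - t/T)`.  Default 2.
#' @param update_rule `"canonical"` uses the leader-guided update
#'   `X_k = X_leader - A_k * D_k`; `"literal"` wraps the displacement in
#'   nested absolute values (`X_k = |X_leader - |A_k * D_k||`), which
#'   confines the search to non-negative coordinates and is provided for
#'   comparison only.
#' @return An object of class `gwo_config`.
#' @export
gwo_config <- function(n_wolves = 30, n_iterations = 100,
                       bounds = c(0, 1), seed = 0, a_initial = 2,
                       update_rule = c("canonical", "literal")) {
  check_scalar(n_wolves, "n_wolves", lower = 4, integer = TRUE)
  check_scalar(n_iterations, "n_iterations", lower = 1, integer = TRUE)
  check_scalar(seed, "seed")
  check_scalar(a_initial, "a_initial", lower = 0)
  update_rule <- match.arg(update_rule)
  if (is.matrix(bounds)) {
    if (ncol(bounds) != 2L) stop_ecgwo("bounds matrix must have 2 columns")
  } else if (!(is.numeric(bounds) && length(bounds) == 2L)) {
    stop_ecgwo("bounds must be c(lower, upper) or a dim x 2 matrix")
  }
  lo <- if (is.matrix(bounds)) bounds[, 1] else bounds[1]
  hi <- if (is.matrix(bounds)) bounds[, 2] else bounds[2]
  if (any(lo >= hi)) stop_ecgwo("each lower bound must be < its upper bound")
  structure(list(n_wolves = as.integer(n_wolves),
                 n_iterations = as.integer(n_iterations),
                 bounds = bounds, leader_count = 3L,
                 seed = as.integer(seed), a_initial = a_initial,
                 update_rule = update_rule),
            class = "gwo_config")
}

expand_bounds <- function(bounds, dim) {
  if (is.matrix(bounds)) {
    if (nrow(bounds) != dim)
      stop_ecgwo("bounds matrix has %d rows but dim is %d", nrow(bounds), dim)
    bounds
  } else {
    matrix(rep(bounds, each = dim), dim, 2)
  }
}

better <- function(a, b, sense) {
  if (sense == "minimize") a < b else a > b
}

# run `fun` with the RNG stream stored in `rng`; returns list(value, rng)
advance_rng <- function(rng, fun) {
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  assign(".Random.seed", rng, envir = env)
  value <- fun()
  list(value = value, rng = get(".Random.seed", envir = env))
}

eval_objective <- function(objective, positions, which_wolves = NULL) {
  idx <- if (is.null(which_wolves)) seq_len(nrow(positions)) else which_wolves
  fits <- vapply(idx, function(i) {
    f <- objective(positions[i, ])
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f))
      stop_ecgwo("objective returned a non-finite value for wolf %d", i)
    f
  }, numeric(1))
  fits
}

update_leaders <- function(state, pos, fit) {
  s <- state$sense
  if (better(fit, state$alpha$fitness, s)) {
    state$delta <- state$beta
    state$beta <- state$alpha
    state$alpha <- list(position = pos, fitness = fit)
  } else if (better(fit, state$beta$fitness, s)) {
    state$delta <- state$beta
    state$beta <- list(position = pos, fitness = fit)
  } else if (better(fit, state$delta$fitness, s)) {
    state$delta <- list(position = pos, fitness = fit)
  }
  state
}

#' Initialize a wolf pack
#'
#' Draws `n_wolves` positions uniformly within the bounds from the seeded
#' generator, evaluates the objective on each, and installs the three best
#' as the alpha, beta, delta leaders.
#'
#' @param config a [gwo_config()].
#' @param dim search-space dimensionality.
#' @param objective function of a numeric vector returning a finite scalar.
#' @param sense `"minimize"` or `"maximize"`.
#' @return A `gwo_state` list: `positions`, `fitnesses`, `alpha`, `beta`,
#'   `delta`, `iteration`, `a`, `rng_state`, plus config echoes.
#' @export
init_pack <- function(config, dim, objective,
                      sense = c("minimize", "maximize")) {
  sense <- match.arg(sense)
  if (!inherits(config, "gwo_config")) stop_ecgwo("config must be a gwo_config")
  check_scalar(dim, "dim", lower = 1, integer = TRUE)
  b <- expand_bounds(config$bounds, dim)
  seeded <- with_seed(config$seed, {
    pos <- matrix(stats::runif(config$n_wolves * dim,
                               min = rep(b[, 1], each = config$n_wolves),
                               max = rep(b[, 2], each = config$n_wolves)),
                  config$n_wolves, dim)
    list(pos = pos, rng = get(".Random.seed", envir = globalenv()))
  })
  pos <- seeded$pos
  fits <- eval_objective(objective, pos)
  ord <- order(fits, decreasing = (sense == "maximize"))
  state <- list(positions = pos, fitnesses = fits,
                alpha = list(position = pos[ord[1], ], fitness = fits[ord[1]]),
                beta  = list(position = pos[ord[2], ], fitness = fits[ord[2]]),
                delta = list(position = pos[ord[3], ], fitness = fits[ord[3]]),
                iteration = 0L, a = config$a_initial,
                bounds = b, sense = sense, config = config,
                rng_state = seeded$rng)
  class(state) <- "gwo_state"
  state
}

#' Stochastic GWO coefficient vectors
#'
#' Per dimension, `A = 2*a*r1 - a` and `C = 2*r2` with `r1, r2 ~ U(0,1)`
#' drawn fresh, so `A` lies in `[-a, a]` and `C` in `[0, 2]`.  `r1`/`r2`
#' may be supplied explicitly for deterministic evaluation.
#'
#' @param a control scalar in `[0, a_initial]`.
#' @param dim number of dimensions.
#' @param r1,r2 optional uniform draws (length `dim`); drawn from the
#'   current RNG stream when omitted.
#' @return List with vectors `A` and `C`.
#' @export
gwo_coefficients <- function(a, dim, r1 = NULL, r2 = NULL) {
  check_scalar(a, "a", lower = 0)
  if (is.null(r1)) r1 <- stats::runif(dim)
  if (is.null(r2)) r2 <- stats::runif(dim)
  list(A = 2 * a * r1 - a, C = 2 * r2)
}

#' Encircling distance
#'
#' Componentwise distance `D = |C * prey - wolf|` between a wolf and the
#' (coefficient-perturbed) prey position.
#'
#' @param C coefficient vector.
#' @param prey prey (leader) position.
#' @param wolf wolf position.
#' @return Non-negative numeric vector.
#' @export
encircle_distance <- function(C, prey, wolf) {
  if (length(C) != length(prey) || length(prey) != length(wolf))
    stop_ecgwo("C, prey and wolf must have equal dimension")
  abs(C * prey - wolf)
}

#' Leader-guided position update
#'
#' Moves one wolf toward the stochastic average of the three leaders:
#' for each leader k in (alpha, beta, delta), fresh coefficients (A_k, C_k)
#' give `D_k = |C_k * X_k - X|` and `X'_k = X_k - A_k * D_k`; the new
#' position is `(X'_alpha + X'_beta + X'_delta) / 3`, clamped to bounds.
#'
#' @param state a `gwo_state` (leaders populated).
#' @param wolf current position vector.
#' @return New position vector within bounds.  Consumes random draws from
#'   the current RNG stream.
#' @export
leader_guided_position <- function(state, wolf) {
  dim <- length(wolf)
  rule <- state$config$update_rule
  xs <- lapply(list(state$alpha, state$beta, state$delta), function(leader) {
    co <- gwo_coefficients(state$a, dim)
    D <- encircle_distance(co$C, leader$position, wolf)
    if (rule == "literal") abs(leader$position - abs(co$A * D))
    else leader$position - co$A * D
  })
  new <- (xs[[1]] + xs[[2]] + xs[[3]]) / 3
  pmin(pmax(new, state$bounds[, 1]), state$bounds[, 2])
}

#' Advance the pack by one iteration
#'
#' Every wolf is moved by [leader_guided_position()], fitnesses are
#' re-evaluated, leaders are replaced only by improvements, the iteration
#' counter advances, and the control scalar is rescheduled to
#' `a_initial * (1 - t/T)`.
#'
#' @param state a `gwo_state`.
#' @param objective the fitness function.
#' @return The updated `gwo_state`.
#' @export
gwo_step <- function(state, objective) {
  n <- nrow(state$positions)
  moved <- advance_rng(state$rng_state, function() {
    newpos <- state$positions
    for (i in seq_len(n))
      newpos[i, ] <- leader_guided_position(state, state$positions[i, ])
    newpos
  })
  state$rng_state <- moved$rng
  state$positions <- moved$value
  state$fitnesses <- eval_objective(objective, state$positions)
  for (i in seq_len(n))
    state <- update_leaders(state, state$positions[i, ], state$fitnesses[i])
  state$iteration <- state$iteration + 1L
  Tt <- state$config$n_iterations
  state$a <- state$config$a_initial * (1 - state$iteration / Tt)
  state
}

#' Run the grey wolf optimizer
#'
#' Initializes a pack and runs `n_iterations` leader-guided updates,
#' tracking the best-so-far (alpha) fitness.  Seeded runs are
#' bit-reproducible.
#'
#' @param objective function mapping a numeric vector of length `dim` to a
#'   finite scalar fitness.
#' @param dim search-space dimensionality.
#' @param sense `"minimize"` (default; benchmark functions) or
#'   `"maximize"` (entropy fitness).
#' @param config a [gwo_config()].
#' @return An object of class `gwo` with `best_position`, `best_fitness`,
#'   `trace` (length `n_iterations + 1`, starting at the initial alpha
#'   fitness), the final `state`, and echoes of `dim`, `sense`, `config`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' fit <- gwo(sphere, dim = 2, config = gwo_config(
#'   n_wolves = 20, n_iterations = 50, bounds = c(-5, 5), seed = 1))
#' fit$best_fitness
#' @export
gwo <- function(objective, dim, sense = c("minimize", "maximize"),
                config = gwo_config()) {
  sense <- match.arg(sense)
  state <- init_pack(config, dim, objective, sense)
  trace <- numeric(config$n_iterations + 1L)
  trace[1] <- state$alpha$fitness
  for (t in seq_len(config$n_iterations)) {
    state <- gwo_step(state, objective)
    trace[t + 1L] <- state$alpha$fitness
  }
  structure(list(best_position = state$alpha$position,
                 best_fitness = state$alpha$fitness,
                 trace = trace, state = state, dim = dim,
                 sense = sense, config = config),
            class = "gwo")
}

#' @export
print.gwo <- function(x, ...) {
  cat(sprintf(
    "Grey wolf optimizer: %d wolves, %d iterations, dim %d (%s)\n",
    x$config$n_wolves, x$config$n_iterations, x$dim, x$sense))
  cat(sprintf("  best fitness: %g\n", x$best_fitness))
  invisible(x)
}

#' @export
coef.gwo <- function(object, ...) object$best_position

#' @export
plot.gwo <- function(x, ...) {
  graphics::plot(seq_along(x$trace) - 1L, x$trace, type = "l",
                 xlab = "iteration", ylab = "best-so-far fitness",
                 main = "GWO convergence", ...)
  invisible(x)
}

#' Analytic benchmark objectives
#'
#' `benchmark_sphere` is `sum(x^2)` (global minimum 0 at the origin);
#' `benchmark_rastrigin` is `10*d + sum(x^2 - 10*cos(2*pi*x))` (highly
#' multimodal, global minimum 0 at the origin).  Used to validate the
#' optimizer's convergence behaviour.
#'
#' @param x numeric vector.
#' @return Scalar objective value.
#' @export
benchmark_sphere <- function(x) sum(x^2)

#' @rdname benchmark_sphere
#' @export
benchmark_rastrigin <- function(x) {
  10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))
}
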
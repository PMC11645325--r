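#' Settings for the adaptive tabu simulated annealing optimizer
#'
#' Bundles every knob of [atsa_optimize()].  The defaults follow the
#' annealer configuration used to tune the LAMA gradient-boosting models:
#' floor temperature 2, reheat multiplier 2, tabu capacity 20, 300
#' temperature levels with 8 candidate moves each, uniform initial
#' solution and Gaussian neighbourhood moves.  Cooling is geometric
#' (`alpha`), reheating fires after `stall_reheat` consecutive
#' non-improving levels and is capped at `t_init`.
#'
#' @param t_min Floor (termination) temperature, > 0.
#' @param t_init Initial temperature, >= `t_min`.
#' @param beta Reheat multiplier, > 1.
#' @param alpha Geometric cooling multiplier in (0, 1).
#' @param tabu_length Capacity of the FIFO tabu list.
#' @param n_iterations Number of temperature levels.
#' @param n_moves Candidate neighbours generated per level.
#' @param stall_reheat Non-improving levels before a reheat; `Inf`
#'   disables reheating (the run then stops once the floor is reached).
#' @param step_scale Neighbourhood step: the standard-normal perturbation
#'   on each axis is scaled by `step_scale * (upper - lower)`.  Scalar or
#'   a named per-axis vector.  Setting `step_scale = 1/(upper - lower)`
#'   recovers a literal unit-variance step on that axis.
#' @param seed Integer seed; every random draw of the run derives from it.
#' @return An object of class `atsa_config`.
#' @export
atsa_config <- function(t_min = 2, t_init = 100, beta = 2, alpha = 0.95,
                        tabu_length = 20, n_iterations = 300, n_moves = 8,
                        stall_reheat = 10, step_scale = 0.1, seed = 1L) {
  stopifnot(t_min > 0, t_init >= t_min, beta > 1, alpha > 0, alpha < 1,
            tabu_length >= 1, n_iterations >= 1, n_moves >= 1,
            stall_reheat >= 1, step_scale >= 0)
  structure(list(t_min = t_min, t_init = t_init, beta = beta, alpha = alpha,
                 tabu_length = as.integer(tabu_length),
                 n_iterations = as.integer(n_iterations),
                 n_moves = as.integer(n_moves), stall_reheat = stall_reheat,
                 step_scale = step_scale, seed = as.integer(seed)),
            class = "atsa_config")
}

#' Draw a uniform random starting solution
#'
#' Each float axis is drawn uniformly over its range; each integer axis
#' uniformly over its integer grid.  Uses the current RNG state: seed with
#' `set.seed()` (or rely on [atsa_optimize()], which seeds once per run).
#'
#' @param space A [search_space()].
#' @return A named numeric vector, one value per axis.
#' @export
init_solution <- function(space) {
  vals <- vapply(space, function(s) {
    if (s$kind == "integer") {
      s$lower - 1 + sample.int(s$upper - s$lower + 1, 1L)
    } else {
      lo <- .axis_floor(s)
      stats::runif(1, lo, s$upper)
    }
  }, numeric(1))
  names(vals) <- names(space)
  vals
}

#' Propose a Gaussian neighbour of a solution
#'
#' Perturbs every axis by a standard-normal draw scaled by
#' `step_scale * (upper - lower)`, rounds integer axes half away from
#' zero, and clips back into bounds.
#'
#' @param sol Named numeric vector valid for `space`.
#' @param space A [search_space()].
#' @param step_scale Fraction of each axis range used as the step
#'   standard deviation (see [atsa_config()]).
#' @return A neighbouring solution (named numeric vector).
#' @export
propose_neighbor <- function(sol, space, step_scale = 0.1) {
  eps <- stats::rnorm(length(space))
  rng <- vapply(space, function(s) s$upper - s$lower, numeric(1))
  if (length(step_scale) > 1L) step_scale <- step_scale[names(space)]
  raw <- sol[names(space)] + step_scale * rng * eps
  .clip_solution(raw, space)
}

#' Metropolis acceptance rule (maximization convention)
#'
#' Accepts any non-worsening move; a worsening move (`delta < 0`) is
#' accepted with probability `exp(delta / temperature)`.
#'
#' @param delta Candidate objective minus current objective.
#' @param temperature Current temperature, > 0.
#' @return `TRUE` to accept the candidate.
#' @export
metropolis_accept <- function(delta, temperature) {
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive", call. = FALSE)
  if (delta >= 0) return(TRUE)
  stats::runif(1) < exp(delta / temperature)
}

#' Adaptive temperature update: cool, or reheat on stagnation
#'
#' Geometric cooling `T <- max(alpha * T, t_min)` whenever the level
#' improved the best-so-far (the stall counter resets) or stagnation is
#' below threshold (the counter increments).  Once `stall_reheat`
#' consecutive non-improving levels accumulate, the temperature is
#' reheated to `min(beta * T, t_init)` and the counter resets.
#'
#' @param temperature Current temperature.
#' @param stall_count Consecutive non-improving levels so far.
#' @param improved Did this level improve the best-so-far value?
#' @param config An [atsa_config()].
#' @return List with elements `temperature`, `stall_count`, and `reheated`.
#' @export
update_temperature <- function(temperature, stall_count, improved, config) {
  if (improved) {
    list(temperature = max(config$alpha * temperature, config$t_min),
         stall_count = 0L, reheated = FALSE)
  } else if (stall_count + 1L >= config$stall_reheat) {
    list(temperature = min(config$beta * temperature, config$t_init),
         stall_count = 0L, reheated = TRUE)
  } else {
    list(temperature = max(config$alpha * temperature, config$t_min),
         stall_count = stall_count + 1L, reheated = FALSE)
  }
}

#' Tabu key of a solution
#'
#' Deterministic string key used for tabu-list membership.  Integer axes
#' enter exactly; float axes are quantized to a grid of `resolution`
#' steps across the axis range, so two float values less than half a grid
#' step apart collide (exact float equality would make the tabu list
#' vacuous).
#'
#' @param sol Named numeric vector valid for `space`.
#' @param space A [search_space()].
#' @param resolution Number of grid steps per float axis range.
#' @return A single string.
#' @export
tabu_key <- function(sol, space, resolution = 1000L) {
  parts <- vapply(space, function(s) {
    v <- sol[[s$name]]
    if (s$kind == "integer") sprintf("%d", as.integer(round(v)))
    else sprintf("%d", as.integer(round((v - s$lower) /
                                          (s$upper - s$lower) * resolution)))
  }, character(1))
  paste(parts, collapse = "|")
}

# fixed-capacity FIFO of keys; returns updated character vector
.tabu_push <- function(tabu, key, capacity) {
  tabu <- c(tabu, key)
  if (length(tabu) > capacity) tabu <- tabu[-1L]
  tabu
}

#' Adaptive tabu simulated annealing over a bounded mixed search space
#'
#' Maximizes a black-box objective over a [search_space()] of integer and
#' float axes.  The search starts from a uniform random solution and runs
#' `n_iterations` temperature levels; at each level up to `n_moves`
#' Gaussian neighbours of the current solution are generated, tabu
#' candidates being regenerated up to 5 times then skipped.  Every
#' evaluated candidate is recorded in a fixed-capacity FIFO tabu list.
#' Moves are accepted by the Metropolis rule; the best-so-far solution is
#' tracked separately (strict improvement only, so ties keep the earlier
#' solution).  Temperature follows [update_temperature()]: geometric
#' cooling with a floor at `t_min` and reheating after `stall_reheat`
#' stagnant levels.  The run is fully reproducible for a fixed
#' `config$seed`.
#'
#' @param objective Function mapping a named numeric vector (solution) to
#'   a single finite number to be maximized.  Errors it raises are
#'   propagated, annotated with the offending solution.
#' @param space A [search_space()].
#' @param config An [atsa_config()].
#' @return List of class `atsa_result`: `best` (named numeric vector),
#'   `best_value`, `trace` (data.frame with one row per evaluated
#'   candidate: `iteration`, `temperature`, `candidate_value`,
#'   `best_value`), `n_evals`, and the `config`.
#' @examples
#' res <- atsa_optimize(function(s) -(s[["x"]] - 3)^2,
#'                      search_space(param_spec("x", "float", 0, 10)),
#'                      atsa_config(n_iterations = 50, seed = 7))
#' res$best
#' @export
atsa_optimize <- function(objective, space, config = atsa_config()) {
  stopifnot(inherits(space, "search_space"), inherits(config, "atsa_config"))
  set.seed(config$seed)

  eval_obj <- function(sol) {
    v <- tryCatch(objective(sol), error = function(e)
      stop("objective failed at solution [",
           paste(sprintf("%s=%g", names(sol), sol), collapse = ", "),
           "]: ", conditionMessage(e), call. = FALSE))
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("objective must return a single finite number", call. = FALSE)
    as.numeric(v)
  }

  current <- init_solution(space)
  current_value <- eval_obj(current)
  best <- current
  best_value <- current_value
  tabu <- .tabu_push(character(0), tabu_key(current, space), config$tabu_length)

  temperature <- config$t_init
  stall <- 0L
  n_evals <- 1L
  tr_iter <- integer(0); tr_temp <- tr_cand <- tr_best <- numeric(0)

  for (iter in seq_len(config$n_iterations)) {
    improved <- FALSE
    for (m in seq_len(config$n_moves)) {
      cand <- NULL
      for (try in 1:5) {
        prop <- propose_neighbor(current, space, config$step_scale)
        if (!(tabu_key(prop, space) %in% tabu)) { cand <- prop; break }
      }
      if (is.null(cand)) next  # all regenerations tabu: skip this move
      value <- eval_obj(cand)
      n_evals <- n_evals + 1L
      tabu <- .tabu_push(tabu, tabu_key(cand, space), config$tabu_length)
      if (value > best_value) {
        best <- cand; best_value <- value; improved <- TRUE
      }
      if (metropolis_accept(value - current_value, temperature)) {
        current <- cand; current_value <- value
      }
      tr_iter <- c(tr_iter, iter); tr_temp <- c(tr_temp, temperature)
      tr_cand <- c(tr_cand, value); tr_best <- c(tr_best, best_value)
    }
    upd <- update_temperature(temperature, stall, improved, config)
    at_floor <- !upd$reheated && config$alpha * temperature < config$t_min
    temperature <- upd$temperature
    stall <- upd$stall_count
    # with reheating disabled no reheat is ever pending: stop at the floor
    if (at_floor && is.infinite(config$stall_reheat)) break
  }

  structure(list(
    best = best, best_value = best_value,
    trace = data.frame(iteration = tr_iter, temperature = tr_temp,
                       candidate_value = tr_cand, best_value = tr_best),
    n_evals = n_evals, config = config), class = "atsa_result")
}

#' @export
print.atsa_result <- function(x, ...) {
  cat("ATSA result: best value", format(x$best_value), "after",
      x$n_evals, "evaluations\n")
  cat("best solution:\n")
  print(round(x$best, 6))
  invisible(x)
}

#' Write an optimizer trace as CSV
#'
#' One row per evaluated candidate (`iteration`, `temperature`,
#' `candidate_value`, `best_value`) — enough to redraw a convergence
#' curve.
#'
#' @param result An `atsa_result` from [atsa_optimize()].
#' @param path Output CSV path.
#' @export
write_trace <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}

#' Uniform random-search baseline
#'
#' Evaluates `n` independent uniform draws from the space and returns the
#' best.  Used as a sanity baseline for the annealer in tests.
#'
#' @param objective,space As in [atsa_optimize()].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return List with `best`, `best_value`, `n_evals`.
#' @export
random_search <- function(objective, space, n = 100, seed = 1L) {
  set.seed(seed)
  best <- NULL; best_value <- -Inf
  for (i in seq_len(n)) {
    sol <- init_solution(space)
    v <- objective(sol)
    if (v > best_value) { best <- sol; best_value <- v }
  }
  list(best = best, best_value = best_value, n_evals = n)
}
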
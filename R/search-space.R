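#' Declare one bounded hyperparameter axis
#'
#' A `param_spec` describes a single tunable axis of a search space: its
#' name, whether it is integer- or real-valued, and its inclusive bounds.
#' Float axes may be declared open at the lower bound (e.g. a learning
#' rate on (0, 1]); sampled and perturbed values are then kept strictly
#' above `lower`.
#'
#' @param name Axis name (non-empty string, unique within a space).
#' @param kind `"integer"` or `"float"`.
#' @param lower,upper Bounds, `lower < upper`; integer axes require
#'   integer bounds.
#' @param lower_open For float axes, whether the lower bound is excluded.
#' @return An object of class `param_spec`.
#' @seealso [search_space()], [default_search_space()]
#' @export
param_spec <- function(name, kind = c("float", "integer"), lower, upper,
                       lower_open = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(lower), is.numeric(upper), length(lower) == 1L,
            length(upper) == 1L, is.finite(lower), is.finite(upper))
  if (lower >= upper)
    stop("param_spec '", name, "': lower must be < upper", call. = FALSE)
  if (kind == "integer") {
    if (lower != round(lower) || upper != round(upper))
      stop("param_spec '", name, "': integer axis needs integer bounds",
           call. = FALSE)
    lower_open <- FALSE
  }
  structure(list(name = name, kind = kind, lower = lower, upper = upper,
                 lower_open = isTRUE(lower_open)),
            class = "param_spec")
}

#' Assemble an ordered hyperparameter search space
#'
#' @param ... `param_spec` objects (or a single list of them).
#' @return An object of class `search_space`: an ordered, uniquely named
#'   list of axes.
#' @examples
#' sp <- search_space(param_spec("x", "float", 0, 10))
#' @export
search_space <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1]]) &&
      !inherits(specs[[1]], "param_spec"))
    specs <- specs[[1]]
  if (length(specs) == 0L) stop("search space must be non-empty", call. = FALSE)
  ok <- vapply(specs, inherits, logical(1), "param_spec")
  if (!all(ok)) stop("all arguments must be param_spec objects", call. = FALSE)
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("axis names must be unique", call. = FALSE)
  names(specs) <- nm
  structure(specs, class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat("search_space with", length(x), "axes:\n")
  for (s in x) {
    cat(sprintf("  %-18s %-7s %s%g, %g]\n", s$name, s$kind,
                if (s$lower_open) "(" else "[", s$lower, s$upper))
  }
  invisible(x)
}

#' Default XGBoost tuning space
#'
#' The eight gradient-boosting hyperparameters tuned by the LAMA
#' prediction framework, with their experimental ranges: number of
#' estimators, maximum depth, maximum delta step and number of parallel
#' trees on the integer grid \[1, 50\]; learning rate, L1 and L2
#' regularization on (0, 1\]; gamma (minimum split loss) on (0, 50\].
#'
#' @return A [search_space()] with the eight axes.
#' @export
default_search_space <- function() {
  search_space(
    param_spec("n_estimators",      "integer", 1, 50),
    param_spec("max_depth",         "integer", 1, 50),
    param_spec("max_delta_step",    "integer", 1, 50),
    param_spec("num_parallel_tree", "integer", 1, 50),
    param_spec("learning_rate",     "float", 0, 1,  lower_open = TRUE),
    param_spec("reg_alpha",         "float", 0, 1,  lower_open = TRUE),
    param_spec("reg_lambda",        "float", 0, 1,  lower_open = TRUE),
    param_spec("gamma",             "float", 0, 50, lower_open = TRUE)
  )
}

# smallest admissible value on an axis (open lower bounds get a hair above)
.axis_floor <- function(spec) {
  if (spec$lower_open) spec$lower + 1e-8 * (spec$upper - spec$lower)
  else spec$lower
}

#' Validate a solution against a search space
#'
#' A solution is a named numeric vector (or named list) with one value per
#' axis, each within bounds, integer axes holding integers.
#'
#' @param sol Named numeric vector or list.
#' @param space A [search_space()].
#' @return The solution as a named numeric vector, invisibly validated.
#' @export
validate_solution <- function(sol, space) {
  sol <- unlist(sol)
  if (!setequal(names(sol), names(space)))
    stop("solution names do not match search space axes", call. = FALSE)
  sol <- sol[names(space)]
  for (s in space) {
    v <- sol[[s$name]]
    lo <- .axis_floor(s)
    if (!is.finite(v) || v < lo || v > s$upper)
      stop("solution value for '", s$name, "' out of bounds", call. = FALSE)
    if (s$kind == "integer" && v != round(v))
      stop("solution value for '", s$name, "' must be integer", call. = FALSE)
  }
  sol
}

# clip a raw numeric vector onto the space (round integer axes half away
# from zero first, then clamp)
.clip_solution <- function(vals, space) {
  out <- vals[names(space)]
  for (s in space) {
    v <- out[[s$name]]
    if (s$kind == "integer") v <- sign(v) * floor(abs(v) + 0.5)
    v <- min(max(v, .axis_floor(s)), s$upper)
    if (s$kind == "integer") v <- round(v)  # floor may reintroduce fractions
    out[[s$name]] <- v
  }
  out
}

#' Read / write search spaces and ATSA settings as YAML
#'
#' `space_to_yaml()` and `space_from_yaml()` round-trip a [search_space()]
#' through a YAML file; `atsa_config_from_yaml()` reads an [atsa_config()]
#' block.  The file shipped at
#' `system.file("extdata", "default_config.yaml", package = "edlama")`
#' holds the package defaults (the experimental tuning ranges and annealer
#' settings).
#'
#' @param space A [search_space()].
#' @param path File path.
#' @return `space_from_yaml()` returns a [search_space()];
#'   `atsa_config_from_yaml()` an [atsa_config()].
#' @export
space_to_yaml <- function(space, path) {
  blk <- lapply(unname(space), function(s)
    list(name = s$name, kind = s$kind, lower = s$lower, upper = s$upper,
         lower_open = s$lower_open))
  yaml::write_yaml(list(search_space = blk), path)
  invisible(path)
}

#' @rdname space_to_yaml
#' @export
space_from_yaml <- function(path) {
  blk <- yaml::read_yaml(path)$search_space
  search_space(lapply(blk, function(s)
    param_spec(s$name, s$kind, s$lower, s$upper,
               lower_open = isTRUE(s$lower_open))))
}

#' @rdname space_to_yaml
#' @export
atsa_config_from_yaml <- function(path) {
  blk <- yaml::read_yaml(path)$atsa
  do.call(atsa_config, blk)
}
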
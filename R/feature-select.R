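# memoising wrapper around a subset evaluator: the criterion is called at
# most once per distinct subset per selector run
.cached_evaluator <- function(evaluator) {
  cache <- new.env(parent = emptyenv())
  calls <- 0L
  f <- function(subset) {
    key <- paste0("s:", paste(sort(subset), collapse = "\r"))
    if (is.null(cache[[key]])) {
      calls <<- calls + 1L
      cache[[key]] <- evaluator(subset)
    }
    cache[[key]]
  }
  attr(f, "n_calls") <- function() calls
  f
}

#' Sequential forward selection
#'
#' Greedy wrapper selection starting from the empty set: at each step the
#' single feature whose addition maximizes the criterion is added,
#' stopping when the best addition improves the criterion by no more than
#' `tolerance`.  Ties go to the lowest column index, so the path is
#' deterministic given the evaluator.  Subset evaluations are cached.
#'
#' @param evaluator Function mapping a character vector of feature names
#'   to a single number (higher = better).  The empty subset is scored
#'   too (return e.g. 0.5 for an AUC criterion).
#' @param features Character vector of candidate feature names.
#' @param tolerance Minimum improvement to accept a step (default 1e-4).
#' @param max_features Optional cap on the subset size.
#' @return A `feature_subset`: list with `selected` (character vector, in
#'   selection order), `trace` (data.frame `step`, `feature`,
#'   `criterion`), and `n_evals`.
#' @export
sfs <- function(evaluator, features, tolerance = 1e-4, max_features = Inf) {
  stopifnot(length(features) >= 1L)
  ev <- .cached_evaluator(evaluator)
  selected <- character(0)
  current <- ev(selected)
  trace <- data.frame(step = integer(0), feature = character(0),
                      criterion = numeric(0))
  while (length(selected) < min(length(features), max_features)) {
    remaining <- setdiff(features, selected)
    scores <- vapply(remaining, function(f) ev(c(selected, f)), numeric(1))
    best_i <- which.max(scores)           # first max: lowest index wins ties
    if (scores[best_i] - current <= tolerance) break
    selected <- c(selected, remaining[best_i])
    current <- scores[best_i]
    trace <- rbind(trace, data.frame(step = length(selected),
                                     feature = remaining[best_i],
                                     criterion = current))
  }
  structure(list(selected = selected, trace = trace,
                 n_evals = attr(ev, "n_calls")()),
            class = "feature_subset")
}

#' Sequential backward selection
#'
#' Mirror of [sfs()]: starts from the full feature set and greedily
#' removes the feature whose removal maximizes the criterion, stopping
#' when every removal worsens the criterion by more than `tolerance`
#' (i.e. the best removal fails to keep the criterion within `tolerance`
#' of improving it).
#'
#' @inheritParams sfs
#' @param min_features Floor on the subset size (default 1).
#' @return A `feature_subset` (see [sfs()]); `trace$feature` records the
#'   removed feature at each step.
#' @export
sbs <- function(evaluator, features, tolerance = 1e-4, min_features = 1L) {
  stopifnot(length(features) >= 1L)
  ev <- .cached_evaluator(evaluator)
  selected <- features
  current <- ev(selected)
  trace <- data.frame(step = integer(0), feature = character(0),
                      criterion = numeric(0))
  step <- 0L
  while (length(selected) > min_features) {
    scores <- vapply(selected, function(f) ev(setdiff(selected, f)),
                     numeric(1))
    best_i <- which.max(scores)
    if (scores[best_i] - current < -tolerance) break  # every removal worsens
    step <- step + 1L
    removed <- selected[best_i]
    selected <- setdiff(selected, removed)
    current <- scores[best_i]
    trace <- rbind(trace, data.frame(step = step, feature = removed,
                                     criterion = current))
  }
  structure(list(selected = selected, trace = trace,
                 n_evals = attr(ev, "n_calls")()),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat("feature_subset:", length(x$selected), "features after",
      nrow(x$trace), "steps (", x$n_evals, "subset evaluations )\n")
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

# k-fold AUC of a wrapped estimator restricted to a candidate subset; the
# criterion both selectors maximize
.wrapper_evaluator <- function(train_df, estimator = c("dt", "rf"),
                               k = 4L, seed = 1L, num_trees = 100L) {
  estimator <- match.arg(estimator)
  lbl <- .get_label(train_df)
  y <- train_df[[lbl]]
  folds <- make_folds(y, k, seed)
  df <- as.data.frame(train_df)
  function(subset) {
    if (length(subset) == 0L) return(0.5)
    aucs <- vapply(seq_len(max(folds)), function(f) {
      tr <- folds != f; va <- folds == f
      dtr <- df[tr, subset, drop = FALSE]; dtr$.y <- y[tr]
      dva <- df[va, subset, drop = FALSE]
      sc <- if (estimator == "dt") {
        fit <- rpart::rpart(.y ~ ., data = dtr, method = "anova")
        as.numeric(stats::predict(fit, dva))
      } else {
        fit <- ranger::ranger(x = dtr[subset], y = factor(y[tr]),
                              num.trees = num_trees, probability = TRUE,
                              seed = seed, num.threads = 1)
        stats::predict(fit, dva, num.threads = 1)$predictions[, "1"]
      }
      auc_rank(sc, y[va])
    }, numeric(1))
    mean(aucs)
  }
}

#' Run the four wrapper selectors and assemble the five data groups
#'
#' Wraps decision-tree and random-forest estimators with sequential
#' forward and backward selection, each scored by stratified k-fold AUC
#' on the candidate subset, and returns the five feature groups used
#' downstream: `DT_SFS`, `DT_SBS`, `RF_SFS`, `RF_SBS`, and `X_all` (every
#' feature).
#'
#' @param train_df Training `visit_table`.
#' @param k Folds for the wrapper criterion (default 4).
#' @param tolerance Convergence tolerance passed to [sfs()]/[sbs()].
#' @param seed Integer seed (folds and estimators).
#' @param num_trees Random-forest size for the RF wrapper.
#' @param max_features Optional cap on subset sizes.
#' @return List of class `selector_groups`: the five character vectors of
#'   feature names, plus `subsets` (the four `feature_subset` objects).
#' @export
run_selectors <- function(train_df, k = 4L, tolerance = 1e-4, seed = 1L,
                          num_trees = 100L, max_features = Inf) {
  feats <- setdiff(names(train_df), .get_label(train_df))
  ev_dt <- .wrapper_evaluator(train_df, "dt", k, seed, num_trees)
  ev_rf <- .wrapper_evaluator(train_df, "rf", k, seed, num_trees)
  subsets <- list(
    DT_SFS = sfs(ev_dt, feats, tolerance, max_features),
    DT_SBS = sbs(ev_dt, feats, tolerance),
    RF_SFS = sfs(ev_rf, feats, tolerance, max_features),
    RF_SBS = sbs(ev_rf, feats, tolerance))
  groups <- c(lapply(subsets, `[[`, "selected"), list(X_all = feats))
  structure(c(groups, list(subsets = subsets)), class = "selector_groups")
}

#' Tabulate how often each feature was selected
#'
#' Per-feature selection counts across selectors (the usual reading: the
#' more often a feature is selected, the more important it is), plus
#' per-selector subset sizes.
#'
#' @param subsets Named list of character vectors (or `feature_subset`
#'   objects), one per selector.
#' @param features Optional universe of feature names (default: union of
#'   the subsets).
#' @return A `selection_summary` data.frame: one row per feature with a
#'   logical column per selector and a `total` count; attribute
#'   `"per_selector"` holds subset sizes.
#' @export
selection_frequency <- function(subsets, features = NULL) {
  subsets <- lapply(subsets, function(s)
    if (inherits(s, "feature_subset")) s$selected else s)
  if (is.null(features)) features <- unique(unlist(subsets))
  mat <- vapply(subsets, function(s) features %in% s,
                logical(length(features)))
  mat <- matrix(mat, nrow = length(features),
                dimnames = list(features, names(subsets)))
  out <- data.frame(feature = features, mat, check.names = FALSE,
                    row.names = NULL)
  out$total <- rowSums(mat)
  attr(out, "per_selector") <- colSums(mat)
  class(out) <- c("selection_summary", "data.frame")
  out
}

#' Write the selection summary as CSV
#'
#' Feature-by-selector checkmark layout with a `Total` column and a
#' bottom totals row.
#'
#' @param summary A `selection_summary`.
#' @param path Output CSV path.
#' @export
write_selection_report <- function(summary, path) {
  sel_cols <- setdiff(names(summary), c("feature", "total"))
  body <- data.frame(Feature = summary$feature,
                     lapply(summary[sel_cols], function(v)
                       ifelse(v, "x", "")),
                     Total = summary$total, check.names = FALSE)
  totals <- c("Total", as.list(attr(summary, "per_selector")), "")
  body <- rbind(body, stats::setNames(totals, names(body)))
  utils::write.csv(body, path, row.names = FALSE)
  invisible(path)
}
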
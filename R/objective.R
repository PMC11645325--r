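# helpers for the CV-AUC objective handed to the annealer

.get_label <- function(vt) {
  sc <- attr(vt, "schema")
  lbl <- if (!is.null(sc)) sc$label else "lama"
  if (!lbl %in% names(vt)) stop("label column '", lbl, "' missing",
                                call. = FALSE)
  lbl
}

#' Stratified train/test split
#'
#' Splits rows into training and test partitions at the given ratio,
#' stratified by the binary label so the rare LAMA class is represented
#' in both.  The test partition is never rebalanced downstream.
#'
#' @param vt A `visit_table` (or data.frame with a `lama` column).
#' @param ratio Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return List of class `split_indices`: `train`, `test` (row indices).
#' @export
split_train_test <- function(vt, ratio = 0.8, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  y <- vt[[.get_label(vt)]]
  if (min(table(y)) < 2L)
    stop("each class needs at least 2 rows to stratify", call. = FALSE)
  set.seed(seed)
  train <- integer(0)
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    n_tr <- round(length(idx) * ratio)
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)  # both classes in both parts
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  structure(list(train = train, test = setdiff(seq_along(y), train)),
            class = "split_indices")
}

#' Stratified cross-validation folds
#'
#' Assigns each row to one of `k` folds, stratified by label; at very low
#' prevalence this is what keeps every fold populated with positives.
#'
#' @param y Binary label vector.
#' @param k Number of folds, >= 2.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, one per row.
#' @export
make_folds <- function(y, k = 4L, seed = 1L) {
  stopifnot(k >= 2)
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  tab <- table(factor(folds, levels = seq_len(k)), y)
  if (any(tab == 0))
    stop("a fold lost one of the classes; reduce k or increase data",
         call. = FALSE)
  folds
}

#' Rebalance class counts by duplication or deletion
#'
#' Returns row indices (into `y`) of a rebalanced sample: oversampling
#' duplicates existing minority rows at random until the counts match
#' (no synthetic interpolation); undersampling keeps a uniform random
#' subset of the majority.  Original data are untouched — callers subset
#' with the returned indices, which keeps provenance auditable.
#'
#' @param y Binary label vector of the rows to rebalance.
#' @param mode `"oversample"`, `"undersample"`, or `"none"`.
#' @param seed Integer seed.
#' @return Integer vector of (possibly repeated) indices into `y`.
#' @export
rebalance_indices <- function(y, mode = c("oversample", "undersample", "none"),
                              seed = 1L) {
  mode <- match.arg(mode)
  tab <- table(y)
  if (length(tab) < 2L) stop("both classes required", call. = FALSE)
  if (mode == "none") return(seq_along(y))
  set.seed(seed)
  cls <- names(tab)
  minority <- cls[which.min(tab)]
  majority <- cls[cls != minority][1]
  idx_min <- which(y == minority)
  idx_maj <- which(y == majority)
  if (mode == "oversample") {
    extra <- sample(idx_min, length(idx_maj) - length(idx_min),
                    replace = TRUE)
    sort(c(idx_min, idx_maj, extra))
  } else {
    sort(c(idx_min, sample(idx_maj, length(idx_min))))
  }
}

#' @rdname rebalance_indices
#' @param data Data.frame whose rows are rebalanced (label from schema or
#'   `lama`).
#' @return `rebalance()` returns the rebalanced data.frame.
#' @export
rebalance <- function(data, mode = c("oversample", "undersample", "none"),
                      seed = 1L) {
  idx <- rebalance_indices(data[[.get_label(data)]], match.arg(mode), seed)
  data[idx, , drop = FALSE]
}

#' Map a hyperparameter solution to learner parameters
#'
#' Translates a solution over [default_search_space()] axes into the
#' gradient-boosting parameter list (number of boosting rounds, tree
#' depth, maximum delta step, parallel trees per round, learning rate,
#' L1/L2 penalties and minimum split loss — the additive-ensemble
#' objective with complexity penalty `gamma * T + lambda/2 * ||w||^2`).
#' Missing axes fall back to the learner's defaults.
#'
#' @param solution Named numeric vector (a point in the search space).
#' @return List of class `learner_params`.
#' @export
solution_to_params <- function(solution) {
  get <- function(nm, default) if (nm %in% names(solution))
    unname(solution[[nm]]) else default
  structure(list(
    n_estimators      = as.integer(get("n_estimators", 10L)),
    max_depth         = as.integer(get("max_depth", 6L)),
    max_delta_step    = as.integer(get("max_delta_step", 0L)),
    num_parallel_tree = as.integer(get("num_parallel_tree", 1L)),
    learning_rate     = get("learning_rate", 0.3),
    reg_alpha         = get("reg_alpha", 0),
    reg_lambda        = get("reg_lambda", 1),
    gamma             = get("gamma", 0)), class = "learner_params")
}

#' Train the gradient-boosted classifier
#'
#' Fits a binary XGBoost model (logistic objective) under the given
#' parameters, single-threaded and seeded, and returns a scoring handle.
#'
#' @param params A `learner_params` (see [solution_to_params()]) or a
#'   named solution vector.
#' @param X Numeric feature matrix (or data.frame of numeric columns).
#' @param y Binary 0/1 label vector.
#' @param seed Integer seed.
#' @return A `lama_model`: list with the fitted booster, feature names,
#'   and `params`.  Score with [predict_scores()].
#' @export
train_learner <- function(params, X, y, seed = 1L) {
  if (!inherits(params, "learner_params")) params <- solution_to_params(params)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y))
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = params$max_depth,
                  max_delta_step = params$max_delta_step,
                  num_parallel_tree = params$num_parallel_tree,
                  eta = params$learning_rate,
                  alpha = params$reg_alpha,
                  lambda = params$reg_lambda,
                  gamma = params$gamma,
                  tree_method = "hist",
                  nthread = 1, seed = as.integer(seed)),
    data = dtrain, nrounds = params$n_estimators, verbose = 0)
  structure(list(booster = booster, features = colnames(X), params = params),
            class = "lama_model")
}

#' Score visits with a fitted model
#'
#' @param model A `lama_model` from [train_learner()].
#' @param X Feature matrix/data.frame with the model's feature columns.
#' @param margin Return raw log-odds margins instead of probabilities.
#' @return Numeric vector of class-1 (LAMA) probabilities (or margins).
#' @export
predict_scores <- function(model, X, margin = FALSE) {
  X <- as.matrix(as.data.frame(X)[, model$features, drop = FALSE])
  storage.mode(X) <- "double"
  stats::predict(model$booster, xgboost::xgb.DMatrix(X),
                 outputmargin = margin)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a random positive outranks a random negative, ties
#' counted one half — computed from the rank sum of the positive class
#' with midranks, so tied scores contribute 1/2 per tied pair.
#'
#' @param scores Numeric scores (higher = more LAMA-like).
#' @param labels Binary 0/1 (or logical) labels.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes required for AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold classification metrics
#'
#' Accuracy, AUC, sensitivity (recall on LAMA = class 1) and specificity
#' (on SAT = class 0) at a fixed probability threshold.
#'
#' @param scores Class-1 scores.
#' @param labels Binary 0/1 labels.
#' @param threshold Classification threshold (default 0.5).
#' @return Named numeric vector: `accuracy`, `auc`, `sensitivity`,
#'   `specificity`.
#' @export
metric_suite <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  c(accuracy = (tp + tn) / length(labels),
    auc = auc_rank(scores, labels),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp))
}

#' Cross-validated evaluation of one hyperparameter solution
#'
#' The model-development protocol behind the tuning objective: for each
#' of `k` stratified folds, the other k−1 folds are rebalanced
#' (oversampling duplicates minority rows, undersampling thins the
#' majority — fitting portion only, the held-out fold is never touched),
#' the learner is fitted under `solution`, and the untouched fold is
#' scored.  The mean fold AUC is the scalar the annealer maximizes.
#'
#' @param solution Named numeric solution vector.
#' @param train_df Training `visit_table` (label column per schema).
#' @param k Number of folds (default 4).
#' @param mode Rebalancing mode (`"oversample"`, `"undersample"`,
#'   `"none"`).
#' @param seed Integer seed: fixes folds, rebalancing draws and learner.
#' @param folds Optional precomputed fold assignment (overrides `k`);
#'   pass the same vector across solutions to keep folds fixed within an
#'   optimization run.
#' @return List of class `cv_result`: `folds` (per-fold metric rows),
#'   `mean` and `sd` (named vectors over the four metrics), `mean_auc`,
#'   and `fit_rows` (per-fold list of absolute row indices used for
#'   fitting, for leakage audits).
#' @export
cv_evaluate <- function(solution, train_df, k = 4L,
                        mode = c("oversample", "undersample", "none"),
                        seed = 1L, folds = NULL) {
  mode <- match.arg(mode)
  lbl <- .get_label(train_df)
  y <- train_df[[lbl]]
  if (is.null(folds)) folds <- make_folds(y, k, seed)
  k_eff <- max(folds)
  feat <- setdiff(names(train_df), lbl)
  X <- as.matrix(as.data.frame(train_df)[, feat, drop = FALSE])

  per_fold <- matrix(NA_real_, k_eff, 4,
                     dimnames = list(NULL, c("accuracy", "auc",
                                             "sensitivity", "specificity")))
  fit_rows <- vector("list", k_eff)
  for (f in seq_len(k_eff)) {
    tr <- which(folds != f)
    va <- which(folds == f)
    if (length(unique(y[va])) < 2L || length(unique(y[tr])) < 2L)
      stop("fold ", f, " lacks one of the classes", call. = FALSE)
    rb <- rebalance_indices(y[tr], mode, seed = seed + f)
    rows <- tr[rb]
    fit_rows[[f]] <- rows
    model <- train_learner(solution, X[rows, , drop = FALSE], y[rows],
                           seed = seed)
    sc <- predict_scores(model, X[va, , drop = FALSE])
    per_fold[f, ] <- metric_suite(sc, y[va])
  }
  structure(list(
    folds = as.data.frame(per_fold),
    mean = colMeans(per_fold), sd = apply(per_fold, 2, stats::sd),
    mean_auc = mean(per_fold[, "auc"]),
    fit_rows = fit_rows, fold_assignment = folds), class = "cv_result")
}

#' Build the CV-AUC tuning objective for the annealer
#'
#' Freezes the training table, fold assignment, rebalancing mode and
#' seed, and returns `function(solution) -> mean CV AUC` for
#' [atsa_optimize()].  The fold assignment is drawn once, so every
#' solution is scored on identical folds.
#'
#' @inheritParams cv_evaluate
#' @param tune_rows Optional: size of a stratified subsample of
#'   `train_df` used inside the objective (tune on a subsample, refit on
#'   everything afterwards).  `NULL` uses all rows.
#' @return A function of one solution returning the mean CV AUC.
#' @export
make_cv_objective <- function(train_df, k = 4L,
                              mode = c("oversample", "undersample", "none"),
                              seed = 1L, tune_rows = NULL) {
  mode <- match.arg(mode)
  lbl <- .get_label(train_df)
  if (!is.null(tune_rows) && tune_rows < nrow(train_df)) {
    sub <- split_train_test(train_df, ratio = tune_rows / nrow(train_df),
                            seed = seed)$train
    train_df <- train_df[sub, , drop = FALSE]
  }
  folds <- make_folds(train_df[[lbl]], k, seed)
  y <- train_df[[lbl]]
  feat <- setdiff(names(train_df), lbl)
  X <- as.matrix(as.data.frame(train_df)[, feat, drop = FALSE])
  storage.mode(X) <- "double"
  # the rebalanced fitting rows do not depend on the solution, so the
  # per-fold fitting/validation fixtures are built once per run
  fixtures <- lapply(seq_len(max(folds)), function(f) {
    tr <- which(folds != f); va <- which(folds == f)
    rows <- tr[rebalance_indices(y[tr], mode, seed = seed + f)]
    list(dtrain = xgboost::xgb.DMatrix(X[rows, , drop = FALSE],
                                       label = y[rows], nthread = 1),
         dval = xgboost::xgb.DMatrix(X[va, , drop = FALSE], nthread = 1),
         yval = y[va])
  })
  function(solution) {
    params <- solution_to_params(solution)
    aucs <- vapply(fixtures, function(fx) {
      booster <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth,
                      max_delta_step = params$max_delta_step,
                      num_parallel_tree = params$num_parallel_tree,
                      eta = params$learning_rate,
                      alpha = params$reg_alpha,
                      lambda = params$reg_lambda,
                      gamma = params$gamma,
                      tree_method = "hist",
                      nthread = 1, seed = as.integer(seed)),
        data = fx$dtrain, nrounds = params$n_estimators, verbose = 0)
      auc_rank(stats::predict(booster, fx$dval), fx$yval)
    }, numeric(1))
    mean(aucs)
  }
}

#' Audit a pipeline evaluation for train/validation leakage
#'
#' Verifies, by row-id bookkeeping, that no held-out row ever entered a
#' rebalanced fitting set: every fold's fitting rows must be disjoint
#' from that fold's validation rows, and (when absolute test indices are
#' given) from the test partition.
#'
#' @param cv A `cv_result` from [cv_evaluate()].
#' @param test_rows Optional absolute test-row indices (the `cv_result`
#'   must then have been built on rows disjoint from them — pass
#'   `offset_map` to translate).
#' @param offset_map Optional integer vector mapping the training
#'   table's local row numbers to absolute row ids.
#' @return `TRUE` invisibly; stops with a diagnostic on any leak.
#' @export
audit_leakage <- function(cv, test_rows = NULL, offset_map = NULL) {
  folds <- cv$fold_assignment
  for (f in seq_along(cv$fit_rows)) {
    va <- which(folds == f)
    fit <- cv$fit_rows[[f]]
    if (length(intersect(fit, va)))
      stop("leakage: fold ", f, " validation rows entered its fitting set",
           call. = FALSE)
    if (!is.null(test_rows)) {
      abs_fit <- if (is.null(offset_map)) fit else offset_map[fit]
      if (length(intersect(abs_fit, test_rows)))
        stop("leakage: test rows entered fold ", f, " fitting set",
             call. = FALSE)
    }
  }
  invisible(TRUE)
}
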
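#' Per-instance additive feature attributions
#'
#' Exact additive attributions for the fitted tree ensemble, in log-odds
#' margin units (probability-space attributions would not be additive).
#' Each instance's attributions plus the base value (expected model
#' output) reconstruct its raw prediction — the local-accuracy contract.
#' The reconstruction residual is 1e-6 at unit margin scale and grows
#' with the margin magnitude (the backend accumulates in single
#' precision); a scale-aware guard enforces it.
#'
#' @param model A `lama_model` from [train_learner()].
#' @param X Feature matrix/data.frame covering the model's features.
#' @return An `attribution_matrix`: list with `scores` (instances x
#'   features), `base` (scalar expected output), and `prediction`
#'   (margin per instance).
#' @export
attribute <- function(model, X) {
  X <- as.data.frame(X)
  missing_feat <- setdiff(model$features, names(X))
  if (length(missing_feat))
    stop("table lacks model features: ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  Xm <- as.matrix(X[, model$features, drop = FALSE])
  storage.mode(Xm) <- "double"
  dm <- xgboost::xgb.DMatrix(Xm)
  contrib <- stats::predict(model$booster, dm, predcontrib = TRUE)
  colnames(contrib) <- c(model$features, "BIAS")
  margin <- stats::predict(model$booster, dm, outputmargin = TRUE)
  scores <- contrib[, model$features, drop = FALSE]
  base <- unname(contrib[1, "BIAS"])
  resid <- max(abs(base + rowSums(scores) - margin))
  # the backend accumulates in single precision, so the attainable
  # residual grows with the margin scale and ensemble size; 1e-6 holds at
  # unit scale, the guard here is a sanity bound
  if (is.na(resid) || resid > 1e-5 * max(1, max(abs(margin))))
    stop("local accuracy violated: max residual ", format(resid),
         call. = FALSE)
  structure(list(scores = scores, base = base, prediction = margin),
            class = "attribution_matrix")
}

#' Global attribution summary
#'
#' Ranks features by global importance (mean absolute attribution) and
#' summarizes each feature's direction of effect as the correlation
#' between its attribution and its value — the sign structure a
#' red-high/blue-low beeswarm conveys, reduced to one number.
#'
#' @param attr An `attribution_matrix` from [attribute()].
#' @param X The feature table the attributions were computed on (needed
#'   for the direction summary; omit to skip it).
#' @return An `attribution_summary` data.frame, sorted by descending
#'   importance: `feature`, `importance` (mean |score|), `direction`
#'   (score-value correlation, `NA` for constant columns), `rank`.
#' @export
summarize_attributions <- function(attr, X = NULL) {
  stopifnot(inherits(attr, "attribution_matrix"))
  imp <- colMeans(abs(attr$scores))
  dir <- rep(NA_real_, length(imp))
  if (!is.null(X)) {
    X <- as.data.frame(X)
    for (j in seq_along(imp)) {
      f <- names(imp)[j]
      v <- X[[f]]
      if (stats::sd(v) > 0 && stats::sd(attr$scores[, f]) > 0)
        dir[j] <- stats::cor(attr$scores[, f], v)
    }
  }
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    direction = dir)
  out <- out[order(-out$importance, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("attribution_summary", "data.frame")
  out
}

#' Pairwise interaction grid
#'
#' Decomposes each prediction into main and pairwise interaction effects
#' and aggregates them as mean absolute values: a symmetric feature ×
#' feature matrix with main-effect magnitudes on the diagonal.  The
#' per-instance interaction tensor is checked to sum back to the
#' instance's total attribution (within 1e-6).
#'
#' @param model A `lama_model`.
#' @param X Feature matrix/data.frame.
#' @return An `interaction_grid`: list with `grid` (symmetric matrix,
#'   mean |interaction|, main effects on the diagonal) and `tensor` (the
#'   per-instance array, instances x features x features, margin units).
#' @export
interactions <- function(model, X) {
  X <- as.data.frame(X)
  Xm <- as.matrix(X[, model$features, drop = FALSE])
  storage.mode(Xm) <- "double"
  dm <- xgboost::xgb.DMatrix(Xm)
  inter <- stats::predict(model$booster, dm, predinteraction = TRUE)
  margin <- stats::predict(model$booster, dm, outputmargin = TRUE)
  p <- length(model$features)
  dimnames(inter) <- list(NULL, c(model$features, "BIAS"),
                          c(model$features, "BIAS"))
  total <- apply(inter, 1, sum)
  resid <- max(abs(total - margin))
  if (is.na(resid) || resid > 1e-5 * max(1, max(abs(margin))))
    stop("interaction decomposition does not reconstruct predictions: ",
         format(resid), call. = FALSE)
  tensor <- inter[, seq_len(p), seq_len(p), drop = FALSE]
  # symmetrize before aggregating (backend splits pair effects evenly but
  # guard against asymmetric rounding)
  tensor <- (tensor + aperm(tensor, c(1, 3, 2))) / 2
  grid <- apply(abs(tensor), c(2, 3), mean)
  structure(list(grid = grid, tensor = tensor), class = "interaction_grid")
}

#' Write attribution reports as CSV
#'
#' `write_attribution_summary()` emits the ranked global summary
#' (feature, mean |score|, direction, rank); `write_interaction_grid()`
#' the symmetric mean-|interaction| matrix.  Scores are in log-odds
#' margin units.
#'
#' @param summary An `attribution_summary`.
#' @param grid An `interaction_grid`.
#' @param path Output CSV path.
#' @export
write_attribution_summary <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_attribution_summary
#' @export
write_interaction_grid <- function(grid, path) {
  utils::write.csv(as.data.frame(grid$grid), path, row.names = TRUE)
  invisible(path)
}
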
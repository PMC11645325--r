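# Independent oracles used across the suite.

# all-pairs AUC: count concordant positive-negative pairs, ties 1/2
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# --- brute-force Shapley on a fitted xgboost ensemble -----------------------
# Value function v(S): descend each tree; at a split on a feature in S
# follow the branch for x, otherwise average the children weighted by
# cover.  Shapley values over exhaustive subset enumeration.

xgb_trees <- function(model) {
  dt <- xgboost::xgb.model.dt.tree(model = model$booster)
  split(as.data.frame(dt), as.data.frame(dt)$Tree)
}

tree_value <- function(tree, x, S) {
  node_row <- function(id) tree[tree$ID == id, , drop = FALSE]
  rec <- function(id) {
    nd <- node_row(id)
    if (nd$Feature == "Leaf") return(nd$Gain)
    if (nd$Feature %in% S) {
      branch <- if (x[[nd$Feature]] < nd$Split) nd$Yes else nd$No
      rec(branch)
    } else {
      cy <- node_row(nd$Yes)$Cover
      cn <- node_row(nd$No)$Cover
      (cy * rec(nd$Yes) + cn * rec(nd$No)) / (cy + cn)
    }
  }
  rec(tree$ID[tree$Node == 0])
}

ensemble_value <- function(trees, x, S)
  sum(vapply(trees, tree_value, numeric(1), x = x, S = S))

subsets_of <- function(feats) {
  out <- list(character(0))
  for (f in feats) out <- c(out, lapply(out, c, f))
  out
}

# margin intercept (the booster's fitted base score, in margin units):
# observed margin minus the summed leaf values along the full-feature path
xgb_intercept <- function(model, x) {
  trees <- xgb_trees(model)
  mg <- predict_scores(model, x, margin = TRUE)
  mg - ensemble_value(trees, x, model$features)
}

shapley_brute <- function(model, x, feats = model$features) {
  trees <- xgb_trees(model)
  p <- length(feats)
  phi <- stats::setNames(numeric(p), feats)
  for (j in feats) {
    rest <- setdiff(feats, j)
    for (S in subsets_of(rest)) {
      w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      phi[j] <- phi[j] + w * (ensemble_value(trees, x, c(S, j)) -
                                ensemble_value(trees, x, S))
    }
  }
  list(phi = phi,
       base = ensemble_value(trees, x, character(0)) + xgb_intercept(model, x))
}

# Shapley interaction values (full phi_ij; the backend reports each
# off-diagonal cell as phi_ij / 2)
shapley_interaction_brute <- function(model, x, feats = model$features) {
  trees <- xgb_trees(model)
  p <- length(feats)
  v <- function(S) ensemble_value(trees, x, S)
  phi <- matrix(0, p, p, dimnames = list(feats, feats))
  for (i in feats) for (j in feats) {
    if (i == j) next
    rest <- setdiff(feats, c(i, j))
    for (S in subsets_of(rest)) {
      w <- factorial(length(S)) * factorial(p - length(S) - 2) /
        (2 * factorial(p - 1))
      d <- v(c(S, i, j)) - v(c(S, i)) - v(c(S, j)) + v(S)
      phi[i, j] <- phi[i, j] + w * d
    }
  }
  # phi now matches the backend cell convention: each off-diagonal cell
  # holds half of the unordered pair's total interaction.  Main effects:
  # phi_i minus all its pairwise interaction cells.
  sh <- shapley_brute(model, x, feats)
  diag(phi) <- sh$phi - rowSums(phi)
  phi
}

# --- greedy selection oracles over a tabulated criterion --------------------
# crit: named numeric vector indexed by subset key (sorted, "+"-joined)
subset_key <- function(s) paste0("{", paste(sort(s), collapse = "+"), "}")

greedy_sfs_oracle <- function(crit, features, tolerance) {
  sel <- character(0)
  cur <- crit[[subset_key(sel)]]
  repeat {
    rem <- setdiff(features, sel)
    if (!length(rem)) break
    vals <- vapply(rem, function(f) crit[[subset_key(c(sel, f))]], numeric(1))
    b <- which.max(vals)
    if (vals[b] - cur <= tolerance) break
    sel <- c(sel, rem[b]); cur <- vals[b]
  }
  sel
}

greedy_sbs_oracle <- function(crit, features, tolerance) {
  sel <- features
  cur <- crit[[subset_key(sel)]]
  while (length(sel) > 1) {
    vals <- vapply(sel, function(f) crit[[subset_key(setdiff(sel, f))]],
                   numeric(1))
    b <- which.max(vals)
    if (vals[b] - cur < -tolerance) break
    sel <- setdiff(sel, sel[b]); cur <- vals[b]
  }
  sel
}

# tabulated criterion lookup as an evaluator function
tabulated_evaluator <- function(crit) function(subset) crit[[subset_key(subset)]]
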
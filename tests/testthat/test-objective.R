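test_that("stratified split honours the ratio, keeps both classes, and is reproducible", {
  vt <- planted_table(n = 1000, prevalence = 0.1, seed = 1)
  sp <- split_train_test(vt, 0.8, seed = 2)
  expect_length(sp$train, 800)
  expect_length(sp$test, 200)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_len(1000))
  expect_identical(split_train_test(vt, 0.8, seed = 2)$train, sp$train)

  # rare-class stratification at 0.66% prevalence
  big <- planted_table(n = 2e4, prevalence = 0.0066, effects = numeric(0),
                       seed = 3)
  sp2 <- split_train_test(big, 0.8, seed = 4)
  expect_gt(sum(big$lama[sp2$train]), 0)
  expect_gt(sum(big$lama[sp2$test]), 0)
  # stratified: train prevalence within one count of 80% of positives
  expect_lt(abs(sum(big$lama[sp2$train]) - 0.8 * sum(big$lama)), 1)
})

test_that("rebalancing equalizes class counts exactly as defined", {
  y <- c(rep(0, 990), rep(1, 10))
  under <- rebalance_indices(y, "undersample", seed = 1)
  expect_equal(as.integer(table(y[under])), c(10L, 10L))
  over <- rebalance_indices(y, "oversample", seed = 1)
  expect_equal(as.integer(table(y[over])), c(990L, 990L))
  # every minority row still present at least once; duplicates only
  expect_setequal(intersect(over, which(y == 1)), which(y == 1))
  expect_true(all(over %in% seq_along(y)))
  # balanced input is a no-op up to order
  yb <- rep(c(0, 1), 50)
  expect_setequal(rebalance_indices(yb, "undersample", seed = 2),
                  seq_along(yb))
  expect_error(rebalance_indices(rep(1, 5), "oversample"), "both classes")
})

test_that("rank AUC reproduces hand cases and the all-pairs brute force", {
  expect_equal(auc_rank(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_rank(c(0.2, 0.8), c(1, 0)), 0)
  expect_equal(auc_rank(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_rank(1:4, c(0, 0, 1, 1)), 1)
  expect_equal(auc_rank(rep(1, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auc_rank(1:3, c(1, 1, 1)), "both classes")

  set.seed(5)
  for (i in 1:60) {
    n <- sample(4:200, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- sample(c(rnorm(n %/% 2), round(rnorm(n - n %/% 2), 1)))
    expect_equal(auc_rank(s, y), auc_pairs(s, y), tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  y <- rbinom(300, 1, 0.3)
  s <- rnorm(300) + y
  expect_equal(auc_rank(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("the metric suite matches confusion-count arithmetic", {
  # TP=8, FN=2, TN=5, FP=5
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.2, 5), rep(0.8, 5))
  labels <- c(rep(1, 10), rep(0, 10))
  m <- metric_suite(scores, labels)
  expect_equal(m[["sensitivity"]], 0.8)
  expect_equal(m[["specificity"]], 0.5)
  expect_equal(m[["accuracy"]], 0.65)

  perfect <- metric_suite(labels, labels)
  expect_equal(unname(perfect), c(1, 1, 1, 1))

  all_zero <- metric_suite(rep(0, 10), labels)
  expect_equal(all_zero[["sensitivity"]], 0)
  expect_equal(all_zero[["specificity"]], 1)
  expect_equal(all_zero[["accuracy"]], 0.5)
})

test_that("the learner is deterministic and separates separable data", {
  X <- data.frame(x = c(rnorm(50, -3), rnorm(50, 3)), z = rnorm(100))
  y <- rep(c(0, 1), each = 50)
  sol <- c(n_estimators = 1, max_depth = 1, learning_rate = 0.5,
           reg_lambda = 0.5)
  m1 <- train_learner(sol, X, y, seed = 1)
  expect_equal(auc_rank(predict_scores(m1, X), y), 1)
  m2 <- train_learner(sol, X, y, seed = 1)
  expect_identical(predict_scores(m1, X), predict_scores(m2, X))
  expect_error(train_learner(sol, X, rep(1, 100)), "both classes")
})

test_that("extreme L2 regularization drives predictions to the base rate", {
  set.seed(7)
  X <- data.frame(x = rnorm(400))
  y <- rbinom(400, 1, plogis(2 * X$x))
  spread <- vapply(c(0, 1e6), function(lam) {
    m <- train_learner(c(n_estimators = 20, max_depth = 3,
                         learning_rate = 0.3, reg_lambda = lam), X, y,
                       seed = 1)
    diff(range(predict_scores(m, X)))
  }, numeric(1))
  expect_gt(spread[1], 0.5)
  expect_lt(spread[2], 0.01)   # leaf weights shrunk toward zero
})

test_that("cross-validation rebalances fitting folds only and never leaks", {
  vt <- planted_table(n = 1200, prevalence = 0.08, seed = 8)
  cv <- cv_evaluate(toy_solution(), vt, k = 4, mode = "oversample", seed = 9)
  expect_true(audit_leakage(cv))
  folds <- cv$fold_assignment
  for (f in 1:4) {
    expect_length(intersect(cv$fit_rows[[f]], which(folds == f)), 0)
    # the rebalanced fitting set is class-balanced
    yfit <- vt$lama[cv$fit_rows[[f]]]
    expect_equal(sum(yfit == 0), sum(yfit == 1))
  }
  expect_true(all(cv$folds$auc >= 0 & cv$folds$auc <= 1))
  expect_equal(cv$mean_auc, mean(cv$folds$auc))
  expect_equal(cv$sd[["auc"]], sd(cv$folds$auc))
})

test_that("a constant learner scores exactly 0.5 under the ties rule", {
  vt <- planted_table(n = 600, prevalence = 0.1, effects = numeric(0),
                      seed = 10)
  # gamma so high no split is ever made -> constant predictions
  sol <- c(n_estimators = 2, max_depth = 2, learning_rate = 0.3,
           gamma = 1e6, reg_lambda = 0.5)
  cv <- cv_evaluate(sol, vt, k = 3, mode = "undersample", seed = 11)
  expect_equal(cv$mean_auc, 0.5)
})

test_that("the tuning objective is frozen: same solution, same value, fixed folds", {
  vt <- planted_table(n = 900, prevalence = 0.1, seed = 12)
  obj <- make_cv_objective(vt, k = 3, mode = "oversample", seed = 13)
  v1 <- obj(toy_solution())
  v2 <- obj(toy_solution())
  expect_identical(v1, v2)
  # and identical to the reporting path
  cv <- cv_evaluate(toy_solution(), vt, k = 3, mode = "oversample",
                    seed = 13)
  expect_equal(v1, cv$mean_auc)
})

test_that("leave-one-out style folds are rejected when a fold lacks a class", {
  vt <- planted_table(n = 120, prevalence = 0.05, seed = 14)
  expect_error(make_folds(vt$lama, k = 60, seed = 1), "lost one of the classes")
})
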
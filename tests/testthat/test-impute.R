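test_that("encoding expands categoricals to n-1 dummies with the documented references", {
  g <- generate_visits(generator_config(300, prevalence = 0.2, seed = 1))
  vt <- encode_visits(g$visits)
  # 4-level smoking status -> 3 dummies; binary sex -> 1; 4 locations -> 3
  expect_true(all(c("smoker_current", "smoker_former", "smoker_never")
                  %in% names(vt)))
  expect_false("smoker_unknown" %in% names(vt))
  expect_true("sex_male" %in% names(vt))
  expect_false("sex_female" %in% names(vt))
  expect_setequal(grep("^loc_", names(vt), value = TRUE),
                  c("loc_10025", "loc_10026", "loc_15001"))
  # label coding: LAMA = 1, SAT = 0
  expect_identical(sort(unique(vt$lama)), c(0L, 1L))
  expect_equal(mean(vt$lama), mean(g$visits$ed_disposition == "LAMA"))
  # dummies exhaust their categorical: reference rows are all-zero
  ref <- g$visits$smoking_status == "Unknown"
  expect_true(all(rowSums(vt[ref, c("smoker_current", "smoker_former",
                                    "smoker_never")]) == 0))
  expect_error(
    encode_visits(transform(g$visits, smoking_status = "Vaper")),
    "unknown categories")
})

test_that("repeated vital-sign readings are averaged and timestamps reduced", {
  g <- generate_visits(generator_config(50, prevalence = 0.3, seed = 2))
  raw <- g$visits
  raw$pulse_rate <- NULL
  raw$pulse_rate_1 <- 80
  raw$pulse_rate_2 <- 90
  raw$month <- NULL; raw$hour <- NULL
  raw$arrival_time <- as.POSIXct("2019-03-15 14:30:00", tz = "UTC")
  vt <- encode_visits(raw)
  expect_true(all(vt$pulse_rate == 85))
  expect_true(all(vt$month == 3))
  expect_true(all(vt$hour == 14))
  expect_false("arrival_time" %in% names(vt))
})

test_that("KNN imputation with K=1 copies an exact-duplicate donor", {
  # duplicated-rows fixture: every row has one exact twin
  set.seed(3)
  base <- data.frame(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  dup <- rbind(base, base)
  masked <- dup
  holes <- cbind(sample(1:40, 15), sample(1:3, 15, replace = TRUE))
  for (i in seq_len(nrow(holes))) masked[holes[i, 1], holes[i, 2]] <- NA
  done <- knn_impute(masked, k = 1)
  # nearest-neighbour oracle: exhaustive scan over standardized distances
  for (i in seq_len(nrow(holes))) {
    r <- holes[i, 1]; cl <- names(dup)[holes[i, 2]]
    expect_equal(done[r, cl], dup[r, cl], tolerance = 1e-12,
                 label = sprintf("cell (%d, %s)", r, cl))
  }
})

test_that("imputing a complete table is the identity, and only missing cells change", {
  g <- generate_visits(generator_config(200, prevalence = 0.2, seed = 4))
  expect_identical(knn_impute(g$visits, k = 3), g$visits)

  d <- degrade(g$visits, c(bmi = 0.15, age = 0.1), seed = 5)
  done <- knn_impute(d, k = 3)
  expect_false(anyNA(done[setdiff(names(done), "ed_disposition")]))
  for (cl in names(d)) {
    obs <- !is.na(d[[cl]])
    expect_identical(done[[cl]][obs], d[[cl]][obs],
                     label = paste("observed cells of", cl))
  }
})

test_that("K equidistant neighbours average, and binary cells re-threshold", {
  df <- data.frame(x = c(0, 0, 0, 0), v = c(1, 2, 3, NA),
                   b = c(1, 1, 0, NA))
  done <- knn_impute(df, k = 3)
  expect_equal(done$v[4], 2)         # mean of 3 equidistant donors
  expect_true(done$b[4] %in% c(0, 1))
  expect_equal(done$b[4], 1)         # mean 2/3 thresholded at 0.5
})

test_that("categorical cells are imputed by neighbour majority", {
  df <- data.frame(x = c(0, 0.1, 0, 5), g = c("a", "a", NA, "b"),
                   stringsAsFactors = FALSE)
  done <- knn_impute(df, k = 2)
  expect_identical(done$g[3], "a")
})

test_that("missingness injection hits the configured fraction and is reproducible", {
  set.seed(6)
  df <- as.data.frame(matrix(rnorm(1000 * 10), 1000, 10))
  inj <- inject_missingness(df, 0.1, seed = 7)
  n_masked <- nrow(inj$mask)
  expect_lt(abs(n_masked - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
  expect_identical(inject_missingness(df, 0.1, seed = 7)$mask, inj$mask)
  # masked positions were observed in the source
  expect_false(anyNA(df[cbind(inj$mask$row,
                              match(inj$mask$column, names(df)))]))
  # and are the only NAs in the masked copy
  expect_equal(sum(is.na(inj$masked)), n_masked)
  expect_error(inject_missingness(df, 1.2), "fraction")
})

test_that("MAPE validation scores masked cells only and handles zeros", {
  # arithmetic oracle on a single masked cell: impute 98 against 100 -> 2%
  rep_ <- data.frame(feature = "f", original = 100, imputed = 98)
  expect_equal(100 * abs(rep_$original - rep_$imputed) / rep_$original, 2)

  # duplicated-rows fixture at K = 1: every feature at MAPE 0
  set.seed(8)
  base <- data.frame(a = runif(30, 1, 2), b = runif(30, 5, 9),
                     c = runif(30, 10, 20))
  dup <- rbind(base, base)
  rep0 <- validate_imputation(dup, fraction = 0.08, k = 1, seed = 9)
  mape <- rep0[rep0$metric == "mape_pct", ]
  expect_gt(nrow(mape), 0)
  expect_true(all(mape$value == 0))

  # zero originals are excluded and counted
  dfz <- data.frame(a = c(0, 2:21), b = rnorm(21))
  inj <- inject_missingness(dfz, 0.3, seed = 10)
  done <- knn_impute(inj$masked, k = 2)
  sel <- inj$mask$column == "a"
  if (any(sel)) {
    r <- validate_imputation(dfz, 0.3, k = 2, seed = 10)
    za <- r[r$feature == "a" & r$metric == "mape_pct", ]
    expect_equal(za$n_zero_excluded, sum(dfz$a[inj$mask$row[sel]] == 0))
  }
})

test_that("MAPE shrinks as within-cluster noise shrinks", {
  make_clustered <- function(noise, seed) {
    set.seed(seed)
    centers <- matrix(runif(3 * 4, 10, 20), 3, 4)
    cl <- sample(1:3, 120, replace = TRUE)
    as.data.frame(centers[cl, ] + matrix(rnorm(120 * 4, 0, noise), 120, 4))
  }
  mapes <- vapply(c(2, 0.5, 0.05), function(ns) {
    df <- make_clustered(ns, seed = 11)
    r <- validate_imputation(df, fraction = 0.1, k = 5, seed = 12)
    mean(r$value[r$metric == "mape_pct"])
  }, numeric(1))
  expect_true(all(diff(mapes) < 0))
  expect_lt(mapes[3], 0.5)
})

test_that("the K-grid report lets K be chosen empirically", {
  g <- generate_visits(generator_config(400, prevalence = 0.2, seed = 13))
  complete <- g$visits[complete.cases(g$visits), ]
  r <- validate_imputation(complete, fraction = 0.1, k = c(1, 5), seed = 14)
  expect_setequal(unique(r$k), c(1, 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_imputation_report(r, path, k = 5)
  tab <- read.csv(path, check.names = FALSE)
  expect_named(tab, c("Feature", "MAPE (%)"))
  expect_true(all(tab$`MAPE (%)` >= 0))
})
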
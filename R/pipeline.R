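#' Assemble a pipeline run configuration
#'
#' Collects every stage's settings with the framework defaults: generate
#' (or load) visits, impute, encode, select features, tune the
#' gradient-boosted classifier per data group and sampling mode with the
#' annealer, evaluate on the held-out split, and explain the best model.
#'
#' @param out_dir Output run directory.
#' @param generator A [generator_config()] (used when `input_csv` is
#'   `NULL`).
#' @param input_csv Optional path to a raw visit CSV (empty cells =
#'   missing) used instead of the generator.
#' @param missing_rates Per-column missingness injected after generation
#'   (named vector; `NULL` for none).
#' @param impute_k Donor count for imputation.
#' @param validate_fraction Artificial-missingness fraction for the MAPE
#'   validation report (`NULL` skips validation).
#' @param select Run wrapper feature selection?  If `FALSE` only the
#'   all-features group is modelled.
#' @param selector_trees RF size inside the wrapper criterion.
#' @param selector_tolerance Wrapper convergence tolerance.
#' @param split_ratio Training fraction of the stratified split.
#' @param cv_k Cross-validation folds.
#' @param modes Sampling modes to run (any of `"oversample"`,
#'   `"undersample"`).
#' @param space [search_space()] tuned by the annealer.
#' @param atsa [atsa_config()] for the annealer.
#' @param tune_rows Optional stratified subsample size for the tuning
#'   objective (refit always uses the full training split).
#' @param threshold Classification threshold for the metric report.
#' @param seed Master seed; stage seeds derive from it and are recorded
#'   in the manifest.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(out_dir,
                            generator = generator_config(5000),
                            input_csv = NULL,
                            missing_rates = NULL,
                            impute_k = 5L,
                            validate_fraction = 0.1,
                            select = TRUE,
                            selector_trees = 100L,
                            selector_tolerance = 1e-4,
                            split_ratio = 0.8,
                            cv_k = 4L,
                            modes = c("oversample", "undersample"),
                            space = default_search_space(),
                            atsa = atsa_config(),
                            tune_rows = NULL,
                            threshold = 0.5,
                            seed = 1L) {
  modes <- match.arg(modes, several.ok = TRUE)
  structure(list(out_dir = out_dir, generator = generator,
                 input_csv = input_csv, missing_rates = missing_rates,
                 impute_k = as.integer(impute_k),
                 validate_fraction = validate_fraction, select = select,
                 selector_trees = as.integer(selector_trees),
                 selector_tolerance = selector_tolerance,
                 split_ratio = split_ratio, cv_k = as.integer(cv_k),
                 modes = modes, space = space, atsa = atsa,
                 tune_rows = tune_rows, threshold = threshold,
                 seed = as.integer(seed)), class = "run_config")
}

#' Read / write raw visit tables as CSV
#'
#' Plain CSV with empty cells as the missing-value sentinel.
#'
#' @param path CSV path.
#' @param visits Visit data.frame.
#' @export
read_visits <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(location_id = "character"),
                  na.strings = "")
}

#' @rdname read_visits
#' @export
write_visits <- function(visits, path) {
  utils::write.csv(visits, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full LAMA modelling pipeline
#'
#' Executes generate (or load) -> degrade -> impute (+ MAPE validation)
#' -> encode -> select -> tune x evaluate (one model per data group and
#' sampling mode) -> explain, writing every report to `config$out_dir`:
#' `manifest.json` (seeds, sizes, model table, best-model choices),
#' `imputation_mape.csv`, `feature_selection.csv`,
#' `tuned_parameters.csv`, `performance_metrics.csv` (cross-validation
#' mean ± sd and testing values for accuracy/AUC/sensitivity/
#' specificity per model), per-model annealer traces under `traces/`,
#' and attribution reports for the best model.  The best model is chosen
#' by mean cross-validated AUC; the best-by-test-AUC choice is recorded
#' alongside, and both appear in the manifest.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the run directory, the model table
#'   (data.frame), the best model ids, fitted best model, and reports.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "traces"), showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[edlama] ", ...)
  t0 <- Sys.time()
  stage_time <- list()
  tick <- function(stage, t) stage_time[[stage]] <<-
    round(as.numeric(Sys.time() - t, units = "secs"), 2)

  ## -- data ---------------------------------------------------------------
  ts <- Sys.time()
  if (!is.null(config$input_csv)) {
    say("loading visits from ", config$input_csv)
    raw <- read_visits(config$input_csv)
    truth <- NULL
  } else {
    say("generating ", config$generator$n, " synthetic visits")
    gen <- generate_visits(config$generator)
    raw <- gen$visits
    truth <- gen$truth
  }
  if (!is.null(config$missing_rates))
    raw <- degrade(raw, config$missing_rates, seed = config$seed + 11L)
  write_visits(raw, file.path(config$out_dir, "visits_raw.csv"))
  tick("data", ts)

  ## -- imputation + validation -------------------------------------------
  ts <- Sys.time()
  imput_report <- NULL
  if (!is.null(config$validate_fraction)) {
    complete <- raw[stats::complete.cases(raw), , drop = FALSE]
    if (nrow(complete) > config$impute_k * 4) {
      say("validating imputation on ", nrow(complete), " complete rows")
      imput_report <- validate_imputation(complete,
                                          fraction = config$validate_fraction,
                                          k = config$impute_k,
                                          seed = config$seed + 13L)
      write_imputation_report(imput_report,
                              file.path(config$out_dir,
                                        "imputation_mape.csv"))
    }
  }
  if (anyNA(raw[setdiff(names(raw), "ed_disposition")])) {
    say("imputing missing cells (K=", config$impute_k, ")")
    raw <- knn_impute(raw, k = config$impute_k)
  }
  vt <- encode_visits(raw)
  tick("impute", ts)

  ## -- split --------------------------------------------------------------
  sp <- split_train_test(vt, config$split_ratio, seed = config$seed + 17L)
  train_df <- vt[sp$train, , drop = FALSE]
  attr(train_df, "schema") <- attr(vt, "schema")
  test_df <- vt[sp$test, , drop = FALSE]
  y_test <- test_df[[.get_label(vt)]]

  ## -- feature selection ---------------------------------------------------
  ts <- Sys.time()
  feats <- setdiff(names(vt), .get_label(vt))
  if (isTRUE(config$select)) {
    say("running wrapper feature selection (DT/RF x SFS/SBS)")
    groups <- run_selectors(train_df, k = config$cv_k,
                            tolerance = config$selector_tolerance,
                            seed = config$seed + 19L,
                            num_trees = config$selector_trees)
    summ <- selection_frequency(groups$subsets, features = feats)
    write_selection_report(summ,
                           file.path(config$out_dir, "feature_selection.csv"))
    group_list <- groups[setdiff(names(groups), "subsets")]
  } else {
    group_list <- list(X_all = feats)
  }
  group_list <- Filter(length, group_list)
  tick("select", ts)

  ## -- optimize + evaluate per (group x mode) -----------------------------
  ts <- Sys.time()
  lbl <- .get_label(vt)
  rows <- list()
  tuned <- list()
  fitted <- list()
  cvres <- list()
  for (mode in config$modes) {
    for (g in names(group_list)) {
      id <- paste(g, mode, sep = "_")
      say("tuning ", id, " (", config$atsa$n_iterations, " levels x ",
          config$atsa$n_moves, " moves)")
      cols <- c(group_list[[g]], lbl)
      tr_g <- train_df[, cols, drop = FALSE]
      attr(tr_g, "schema") <- list(kinds = attr(vt, "schema")$kinds[cols],
                                   label = lbl)
      obj <- make_cv_objective(tr_g, k = config$cv_k, mode = mode,
                               seed = config$seed + 23L,
                               tune_rows = config$tune_rows)
      cfg <- config$atsa
      cfg$seed <- config$seed + 29L
      res <- atsa_optimize(obj, config$space, cfg)
      write_trace(res, file.path(config$out_dir, "traces",
                                 paste0(id, ".csv")))
      tuned[[id]] <- res$best
      # full-train CV metrics at the tuned solution (validation folds)
      cv <- cv_evaluate(res$best, tr_g, k = config$cv_k, mode = mode,
                        seed = config$seed + 23L)
      cvres[[id]] <- cv
      # refit on the rebalanced full training split, score the test set
      rb <- rebalance_indices(tr_g[[lbl]], mode, seed = config$seed + 31L)
      model <- train_learner(res$best,
                             tr_g[rb, group_list[[g]], drop = FALSE],
                             tr_g[[lbl]][rb], seed = config$seed + 23L)
      fitted[[id]] <- model
      sc <- predict_scores(model, test_df[, group_list[[g]], drop = FALSE])
      tst <- metric_suite(sc, y_test, config$threshold)
      rows[[id]] <- data.frame(
        model = id, group = g, mode = mode,
        n_features = length(group_list[[g]]),
        cv_accuracy = cv$mean[["accuracy"]], cv_accuracy_sd = cv$sd[["accuracy"]],
        cv_auc = cv$mean[["auc"]], cv_auc_sd = cv$sd[["auc"]],
        cv_sensitivity = cv$mean[["sensitivity"]],
        cv_sensitivity_sd = cv$sd[["sensitivity"]],
        cv_specificity = cv$mean[["specificity"]],
        cv_specificity_sd = cv$sd[["specificity"]],
        test_accuracy = tst[["accuracy"]], test_auc = tst[["auc"]],
        test_sensitivity = tst[["sensitivity"]],
        test_specificity = tst[["specificity"]])
    }
  }
  model_table <- do.call(rbind, rows)
  rownames(model_table) <- NULL
  utils::write.csv(model_table,
                   file.path(config$out_dir, "performance_metrics.csv"),
                   row.names = FALSE)
  tuned_df <- data.frame(model = names(tuned),
                         do.call(rbind, lapply(tuned, function(s)
                           as.data.frame(as.list(s)))),
                         row.names = NULL)
  utils::write.csv(tuned_df,
                   file.path(config$out_dir, "tuned_parameters.csv"),
                   row.names = FALSE)
  tick("optimize", ts)

  ## -- explain the best model ---------------------------------------------
  ts <- Sys.time()
  best_by_cv <- model_table$model[which.max(model_table$cv_auc)]
  best_by_test <- model_table$model[which.max(model_table$test_auc)]
  say("best by mean CV AUC: ", best_by_cv, "; by test AUC: ", best_by_test)
  best_model <- fitted[[best_by_cv]]
  Xtest <- test_df[, best_model$features, drop = FALSE]
  att <- attribute(best_model, Xtest)
  att_summary <- summarize_attributions(att, Xtest)
  write_attribution_summary(att_summary,
                            file.path(config$out_dir,
                                      "attribution_summary.csv"))
  igrid <- interactions(best_model, Xtest)
  write_interaction_grid(igrid,
                         file.path(config$out_dir, "interaction_grid.csv"))
  tick("explain", ts)

  manifest <- list(
    package_version = as.character(utils::packageVersion("edlama")),
    seed = config$seed,
    derived_seeds = list(degrade = config$seed + 11L,
                         validate = config$seed + 13L,
                         split = config$seed + 17L,
                         select = config$seed + 19L,
                         folds_and_learner = config$seed + 23L,
                         atsa = config$seed + 29L,
                         refit_rebalance = config$seed + 31L),
    n_visits = nrow(raw), n_train = length(sp$train),
    n_test = length(sp$test),
    prevalence = mean(vt[[lbl]]),
    groups = lapply(group_list, identity),
    modes = config$modes,
    atsa = unclass(config$atsa),
    best_by_cv_auc = best_by_cv, best_by_test_auc = best_by_test,
    truth = if (!is.null(truth))
      truth[c("effects", "intercept", "bayes_auc")] else NULL,
    stage_seconds = stage_time,
    total_seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(out_dir = config$out_dir, model_table = model_table,
                 tuned = tuned, best_by_cv_auc = best_by_cv,
                 best_by_test_auc = best_by_test,
                 best_model = best_model, cv = cvres,
                 attribution = att_summary, interaction = igrid,
                 imputation = imput_report, split = sp, truth = truth,
                 manifest = manifest))
}
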
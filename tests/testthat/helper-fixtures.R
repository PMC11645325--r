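# Shared fixtures, all generated in code.

# small planted-signal cohort, encoded, with schema attribute preserved
planted_table <- function(n = 1500, prevalence = 0.05,
                          effects = c(esi = 2.5, waiting_time = -1.5),
                          seed = 5) {
  g <- generate_visits(generator_config(n, prevalence = prevalence,
                                        effects = effects, seed = seed))
  encode_visits(g$visits)
}

# subset of a visit_table keeping the schema attribute
vt_subset <- function(vt, rows = NULL, cols = NULL) {
  out <- vt
  if (!is.null(cols)) out <- out[, cols, drop = FALSE]
  if (!is.null(rows)) out <- out[rows, , drop = FALSE]
  attr(out, "schema") <- attr(vt, "schema")
  out
}

# deterministic tiny learner solution used where tuning is not the point
toy_solution <- function()
  c(n_estimators = 15, max_depth = 3, max_delta_step = 1,
    num_parallel_tree = 1, learning_rate = 0.3, reg_alpha = 0.05,
    reg_lambda = 0.5, gamma = 0.05)

# fully tabulated random criterion over all subsets of `features`
random_criterion <- function(features, seed) {
  set.seed(seed)
  subsets <- subsets_of(features)
  keys <- vapply(subsets, subset_key, character(1))
  stats::setNames(runif(length(keys)), keys)
}
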
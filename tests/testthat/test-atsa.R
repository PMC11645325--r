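int_axis <- function(lo = 1, hi = 50)
  search_space(param_spec("k", "integer", lo, hi))
float_axis <- function(lo = 0, hi = 1, open = TRUE)
  search_space(param_spec("x", "float", lo, hi, lower_open = open))

test_that("initial solutions are uniform over the axis", {
  set.seed(1)
  draws <- replicate(1e4, init_solution(int_axis(1, 2))[["k"]])
  expect_true(all(draws %in% 1:2))
  # binomial(1e4, .5): 3 sigma = 150
  expect_lt(abs(mean(draws == 1) - 0.5), 3 * 0.005)

  set.seed(2)
  big <- replicate(5e3, init_solution(int_axis(1, 50))[["k"]])
  expect_true(all(big %in% 1:50))
  expect_gt(length(unique(big)), 45)

  set.seed(3)
  u <- replicate(1e4, init_solution(float_axis())[["x"]])
  expect_true(all(u > 0 & u <= 1))
  # mean of U(0,1): sd of the mean = 1/sqrt(12 * 1e4)
  expect_lt(abs(mean(u) - 0.5), 3 / sqrt(12 * 1e4))
})

test_that("neighbourhood proposals have the configured moments and respect bounds", {
  sp <- float_axis(0, 10, open = FALSE)
  sol <- c(x = 5)
  expect_equal(propose_neighbor(sol, sp, step_scale = 0), sol)

  set.seed(4)
  moves <- replicate(1e4, propose_neighbor(sol, sp, 0.1)[["x"]]) - 5
  expect_lt(abs(mean(moves)), 3 * 1 / sqrt(1e4))   # sd = 0.1*10 = 1
  expect_lt(abs(sd(moves) - 1), 0.05)
  expect_true(all(moves >= -5 & moves <= 5))

  # pinned at the upper bound under a huge step
  set.seed(5)
  top <- replicate(50, propose_neighbor(c(x = 10), sp, 10)[["x"]])
  expect_true(all(top <= 10 & top >= 0))

  # integer axes stay integer
  set.seed(6)
  ints <- replicate(200, propose_neighbor(c(k = 25), int_axis(), 0.1)[["k"]])
  expect_true(all(ints == round(ints) & ints >= 1 & ints <= 50))
})

test_that("metropolis acceptance is calibrated and monotone", {
  expect_true(metropolis_accept(0, 1e-12))
  expect_true(metropolis_accept(2, 0.5))
  expect_error(metropolis_accept(-1, 0), "positive")

  set.seed(7)
  temp <- 3
  acc <- mean(replicate(1e4, metropolis_accept(-temp * log(2), temp)))
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 1e4))

  # nonincreasing in |delta| at fixed T; nondecreasing in T at fixed delta
  rate <- function(delta, temp) {
    set.seed(8)
    mean(replicate(4000, metropolis_accept(delta, temp)))
  }
  r_delta <- vapply(c(-0.5, -1, -2, -4), rate, numeric(1), temp = 1)
  expect_true(all(diff(r_delta) <= 0.02))
  r_temp <- vapply(c(0.5, 1, 2, 4), function(tt) rate(-1, tt), numeric(1))
  expect_true(all(diff(r_temp) >= -0.02))
})

test_that("temperature control cools, clamps, and reheats on stagnation", {
  cfg <- atsa_config(t_min = 2, t_init = 100, beta = 2, alpha = 0.9,
                     stall_reheat = 3)
  # improvement: geometric cooling
  up <- update_temperature(10, 2L, improved = TRUE, cfg)
  expect_equal(up$temperature, 9)
  expect_equal(up$stall_count, 0L)
  # floor clamp
  up <- update_temperature(2, 0L, improved = FALSE, cfg)
  expect_equal(up$temperature, 2)
  expect_equal(up$stall_count, 1L)
  # reheat doubles once the stall threshold is hit
  up <- update_temperature(4, 2L, improved = FALSE, cfg)
  expect_equal(up$temperature, 8)
  expect_true(up$reheated)
  expect_equal(up$stall_count, 0L)
  # reheat capped at t_init
  up <- update_temperature(80, 2L, improved = FALSE, cfg)
  expect_equal(up$temperature, 100)
})

test_that("tabu keys quantize floats and match integers exactly", {
  sp <- search_space(param_spec("k", "integer", 1, 50),
                     param_spec("x", "float", 0, 1, lower_open = TRUE))
  expect_identical(tabu_key(c(k = 3, x = 0.5), sp),
                   tabu_key(c(k = 3, x = 0.5), sp))
  # below half a grid step (range/1000): same key
  expect_identical(tabu_key(c(k = 3, x = 0.5), sp),
                   tabu_key(c(k = 3, x = 0.5 + 2e-4), sp))
  expect_false(identical(tabu_key(c(k = 3, x = 0.5), sp),
                         tabu_key(c(k = 3, x = 0.51), sp)))
  expect_false(identical(tabu_key(c(k = 3, x = 0.5), sp),
                         tabu_key(c(k = 4, x = 0.5), sp)))
})

test_that("a constant objective returns the constant with a flat trace", {
  res <- atsa_optimize(function(s) 7, float_axis(0, 1),
                       atsa_config(n_iterations = 10, seed = 1))
  expect_equal(res$best_value, 7)
  expect_true(all(res$trace$best_value == 7))
})

test_that("runs are bitwise reproducible per seed and traces are monotone", {
  obj <- function(s) -(s[["x"]] - 3)^2
  sp <- float_axis(0, 10, open = FALSE)
  cfg <- atsa_config(n_iterations = 40, seed = 99)
  r1 <- atsa_optimize(obj, sp, cfg)
  r2 <- atsa_optimize(obj, sp, cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best, r2$best)
  expect_true(all(diff(r1$trace$best_value) >= 0))
  expect_true(all(r1$trace$temperature >= cfg$t_min))
  expect_true(all(r1$trace$temperature <= cfg$t_init))
})

test_that("hill-climbing limit: a vanishing temperature accepts no worsening move", {
  # tiny fixed temperature, no reheating: exp(delta/T) underflows for any
  # worsening move, so the current value can never decrease
  sp <- float_axis(0, 10, open = FALSE)
  cfg <- atsa_config(t_min = 1e-12, t_init = 1e-12, alpha = 0.5,
                     stall_reheat = Inf, n_iterations = 60, seed = 13)
  res <- atsa_optimize(function(s) -(s[["x"]] - 3)^2, sp, cfg)
  set.seed(1)
  worsening <- replicate(2000, metropolis_accept(-1e-6, 1e-12))
  expect_equal(sum(worsening), 0)
  expect_true(all(diff(res$trace$best_value) >= 0))
})

test_that("the tabu list caps at capacity with FIFO eviction during a run", {
  # instrumented replica of the optimizer's tabu bookkeeping
  sp <- search_space(param_spec("k", "integer", 1, 5))
  cfg <- atsa_config(tabu_length = 3, n_iterations = 10, n_moves = 4,
                     seed = 2, t_min = 2, t_init = 8)
  set.seed(cfg$seed)
  tabu <- character(0)
  lengths <- integer(0)
  cur <- init_solution(sp)
  tabu <- edlama:::.tabu_push(tabu, tabu_key(cur, sp), cfg$tabu_length)
  keys_seen <- tabu_key(cur, sp)
  for (i in 1:40) {
    cand <- propose_neighbor(cur, sp, 0.5)
    key <- tabu_key(cand, sp)
    prev <- tabu
    tabu <- edlama:::.tabu_push(tabu, key, cfg$tabu_length)
    lengths <- c(lengths, length(tabu))
    if (length(prev) == cfg$tabu_length) {
      expect_identical(tabu, c(prev[-1], key))  # oldest evicted, FIFO
    }
    cur <- cand
  }
  expect_true(all(lengths <= cfg$tabu_length))
})

test_that("objective errors propagate annotated with the solution", {
  sp <- search_space(param_spec("x", "float", 0, 1))
  expect_error(
    atsa_optimize(function(s) stop("boom"), sp,
                  atsa_config(n_iterations = 2, seed = 1)),
    "objective failed at solution.*boom")
})

test_that("the annealer beats random search on a deceptive objective", {
  # two-basin objective: narrow global optimum at x = 9
  obj <- function(s) {
    x <- s[["x"]]
    exp(-((x - 2) / 1.5)^2) + 2 * exp(-((x - 9) / 0.3)^2)
  }
  sp <- search_space(param_spec("x", "float", 0, 10))
  res <- atsa_optimize(obj, sp, atsa_config(n_iterations = 120, seed = 3))
  rs <- random_search(obj, sp, n = res$n_evals, seed = 3)
  expect_gte(res$best_value, rs$best_value - 0.05)
  expect_lt(abs(res$best[["x"]] - 9), 0.2)
})
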
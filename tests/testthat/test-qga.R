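test_that("initialization draws K0 = 2^(S+1) variants and respects the budget", {
  fit3 <- qga(rosenbrock2d(), target_entropy = 3, max_evaluations = 100, seed = 1)
  expect_equal(fit3$K0, 16L)
  fit4 <- qga(rosenbrock2d(), target_entropy = 4, max_evaluations = 100, seed = 1)
  expect_equal(fit4$K0, 32L)

  expect_error(qga(rosenbrock2d(), target_entropy = 4, max_evaluations = 10),
               "K0")
  expect_error(qga(rosenbrock2d(), target_entropy = 0), "positive")
  expect_error(qga(rosenbrock2d(), target_entropy = 4, init_sd = c(1, -1)),
               "positive")
})

test_that("runs are reproducible from the seed", {
  a <- qga(rosenbrock2d(), target_entropy = 3, max_evaluations = 3000, seed = 5)
  b <- qga(rosenbrock2d(), target_entropy = 3, max_evaluations = 3000, seed = 5)
  expect_identical(a$trace, b$trace)
  expect_identical(a$best, b$best)
  expect_identical(a$termination, b$termination)
  c <- qga(rosenbrock2d(), target_entropy = 3, max_evaluations = 3000, seed = 6)
  expect_false(identical(a$trace, c$trace))
})

test_that("the entropy solver hits its target and handles the edge cases", {
  # flat fitness: t = 0 by convention, entropy log2 K
  popflat <- population(matrix(rnorm(8), 4, 2), f = rep(2, 4))
  stf <- solve_selection_scale(popflat, 1)
  expect_equal(stf$t, 0)
  expect_equal(stf$entropy_bits, 2)
  expect_equal(attr(stf, "flag"), "flat")

  # K = 2 with 1-bit target: uniform already achieves the maximum
  pop2 <- population(matrix(rnorm(4), 2, 2), f = c(0, 1))
  st2 <- solve_selection_scale(pop2, 1)
  expect_equal(st2$t, 0)

  # K = 4, f = 0:3, 1-bit target: compare to an independent root finder on
  # the direct (unshifted) entropy formula
  pop4 <- population(matrix(rnorm(8), 4, 2), f = c(0, 1, 2, 3))
  st4 <- solve_selection_scale(pop4, 1, tol = 1e-9)
  expect_equal(st4$entropy_bits, 1, tolerance = 1e-9)
  oracle <- uniroot(function(t) {
    w <- exp(t * c(0, 1, 2, 3))
    entropy_bits_direct(w / sum(w)) - 1
  }, c(0, 20), tol = 1e-12)$root
  expect_equal(st4$t, oracle, tolerance = 1e-6)

  # non-uniform base frequencies are refused (monotonicity not guaranteed)
  popnu <- population(matrix(rnorm(8), 4, 2), f = c(0, 1, 2, 3),
                      p0 = c(0.4, 0.3, 0.2, 0.1))
  expect_error(solve_selection_scale(popnu, 1), "uniform")

  # unreachable target: entropy ceiling log2(K) below the requested S
  st_hi <- solve_selection_scale(pop4, 5)
  expect_equal(attr(st_hi, "flag"), "below_target")
})

test_that("run traces respect the record invariants", {
  fit <- qga(random_quadratic_instance(5, 100, seed = 2), target_entropy = 5,
             max_evaluations = 5e4, seed = 5)
  tr <- fit$trace
  expect_true(all(diff(tr$evals) > 0))
  expect_true(all(diff(tr$best_objective) <= 0))
  expect_equal(tr$K_eff, 2^tr$entropy_bits, tolerance = 1e-12)
  # entropy is pinned at the target after the initial row
  expect_true(all(abs(tr$entropy_bits[-1] - 5) < 1e-5))
  expect_lte(fit$evaluations, 5e4)
  expect_equal(fit$best_objective, -fit$best_fitness)
})

test_that("selection can decrease when a much fitter variant appears", {
  fit <- qga(rosenbrock2d(), target_entropy = 4, max_evaluations = 5e4, seed = 7)
  expect_equal(fit$termination, "converged")
  expect_gt(sum(diff(fit$trace$t) < 0), 0)
})

test_that("convergent quadratic runs show exponential selection growth", {
  fit <- qga(random_quadratic_instance(5, 100, seed = 3), target_entropy = 5,
             max_evaluations = 5e4, seed = 11)
  expect_equal(fit$termination, "converged")
  tr <- fit$trace[fit$trace$t > 0, ]
  last_half <- tr[tr$evals > stats::median(tr$evals), ]
  slope <- stats::coef(stats::lm(log(t) ~ evals, data = last_half))[["evals"]]
  expect_gt(slope, 0)
  # objective gap shrinks by many orders of magnitude
  gap <- tr$best_objective - fit$optimum_objective
  expect_lt(min(gap), 1e-8)
})

test_that("low target entropy causes premature convergence", {
  n_succ <- function(S) {
    sum(vapply(1:20, function(k) {
      land <- random_quadratic_instance(5, 100, seed = 100 + k)
      fit <- qga(land, target_entropy = S, max_evaluations = 5e4,
                 fitness_tolerance = 1e-8, seed = 200 + k)
      identical(fit$termination, "converged")
    }, NA))
  }
  s5 <- n_succ(5)
  s1 <- n_succ(1)
  expect_lt(s1, s5)
})

test_that("a step-quantized landscape triggers the duplicate-fitness stop", {
  floorq <- as_landscape(function(x) floor(sum(x^2)), dim = 3,
                         name = "floorquad",
                         init = list(mean = rep(2, 3), sd = rep(1, 3)))
  fit <- qga(floorq, target_entropy = 3, max_evaluations = 5000, seed = 4)
  expect_equal(fit$termination, "duplicate_fitness")
})

test_that("budget exhaustion is reported when no optimum is known", {
  # no known optimum: only budget/duplicate termination possible
  bowl <- as_landscape(function(x) sum(x^2), dim = 2, name = "bowl",
                       init = list(mean = c(1, 1), sd = c(1, 1)))
  fit <- qga(bowl, target_entropy = 2, max_evaluations = 120, seed = 9)
  expect_true(fit$termination %in% c("budget_exhausted", "duplicate_fitness"))
  expect_gte(fit$evaluations, 8)
})

test_that("qga methods print, summarize, extract, and plot", {
  fit <- qga(rosenbrock2d(), target_entropy = 3, max_evaluations = 2000, seed = 3)
  expect_output(print(fit), "termination")
  expect_output(print(summary(fit)), "best phenotype")
  expect_length(coef(fit), 2)
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})

test_that("run records round-trip through the tabular writer", {
  fit <- qga(rosenbrock2d(), target_entropy = 3, max_evaluations = 1000, seed = 2)
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  write_run_record(fit, tsv, summary_path = js)
  back <- read.delim(tsv)
  expect_equal(names(back), names(fit$trace))
  expect_equal(back$best_objective, fit$trace$best_objective)
  summ <- jsonlite::read_json(js)
  expect_equal(summ$termination, fit$termination)
  expect_equal(summ$seed, 2L)
  expect_equal(unlist(summ$best_phenotype), fit$best, tolerance = 1e-12)
})
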
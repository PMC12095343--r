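# Shared fixtures: small configs and problem generators used across
# test files. Everything is generated in code; no stored data.

quick_cfg <- function(seed = 1L, max_iter = 50L, pop_size = 20L, ...) {
  optimizer_config(pop_size = pop_size, max_iter = max_iter, seed = seed,
                   ...)
}

# random linear allocation problem with admissible variance cap
random_linear_problem <- function(n, seed) {
  withr::with_seed(seed, {
    E <- exp(stats::runif(n, log(0.5), log(2)))
    d2 <- stats::runif(1, 1 / n, 1)
    list(prob = allocation_problem(tibble::tibble(efficiency = E),
                                   delta_sq = d2),
         E = E, delta_sq = d2)
  })
}

expect_feasible <- function(x, prob,
                            tol_sum = 1e-9, tol_nonneg = 1e-12,
                            tol_var = 1e-9) {
  expect_lt(abs(sum(x) - 1), tol_sum)
  expect_true(all(x >= -tol_nonneg))
  expect_lte(sum(x^2), prob$delta_sq + tol_var)
  expect_true(all(x >= prob$targets$lb - 1e-9))
  expect_true(all(x <= prob$targets$ub + 1e-9))
}
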
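# Optimizer contracts, checked on a toy chain where simulation is cheap.
# Target: maximize the terminal metabolite M3 by forcing the first reaction.

toy_cons <- list(M3 = c(0, 4 * toy3$steady_state[["M3"]]))

fit_toy <- optimize_dynamic(toy3, cluster = "R1", horizon = 600,
                            constraints = toy_cons, target = "M3",
                            omega_range = c(2 * pi / 600, 2 * pi / 30),
                            budget = 250, n_starts = 4, seed = 5,
                            dt = 5, rtol = 1e-8, final_dt = 1)

test_that("degenerate zero-amplitude bounds give exactly the baseline", {
  fit0 <- optimize_dynamic(toy3, cluster = "R1", horizon = 600,
                           constraints = toy_cons, target = "M3",
                           A_max = 0, budget = 60, n_starts = 2, seed = 1,
                           dt = 5, final_dt = 1)
  expect_equal(fit0$gain, 1, tolerance = 1e-9)
})

test_that("the optimizer never loses to the feasible baseline", {
  expect_gte(fit_toy$gain, 1)
  expect_true(fit_toy$converged)
})

test_that("the reported optimum is feasible and reproducible from scratch", {
  expect_lt(max(fit_toy$constraint_report$worst_violation), 1e-6)
  re <- simulate_network(toy3, fit_toy$program, horizon = 600, dt = 1,
                         rtol = 1e-8, atol = 1e-11)
  expect_equal(total_metabolite(re, "M3"), fit_toy$objective,
               tolerance = 1e-8)
})

test_that("the optimum dominates a brute-force grid over (A, omega, phi)", {
  grid <- expand.grid(A = c(0, 0.5, 1), w = c(0, 0.5, 1), p = c(0, 0.5, 1))
  best_grid <- -Inf
  for (k in seq_len(nrow(grid))) {
    z <- as.numeric(grid[k, ])
    A <- z[1] * 40
    omega <- 2 * pi / 600 + z[2] * (2 * pi / 30 - 2 * pi / 600)
    prog <- forcing_program(enzyme_profile("R1", "cosine", A = A,
                                           omega = omega,
                                           phi = z[3] * 2 * pi))
    traj <- simulate_network(toy3, prog, horizon = 600, dt = 1,
                             rtol = 1e-8, atol = 1e-11)
    if (max(oscimet:::worst_violations(traj, toy_cons)) <= 1e-6) {
      best_grid <- max(best_grid, total_metabolite(traj, "M3"))
    }
  }
  expect_gte(fit_toy$objective, best_grid - 1e-6)
})

test_that("static optimization at pinned bounds gives gain 1", {
  fit <- optimize_static(toy3, cluster = "R1", horizon = 600,
                         constraints = toy_cons, target = "M3", h_max = 1,
                         budget = 60, n_starts = 2, seed = 1, dt = 5,
                         final_dt = 1)
  # levels confined to [0, 1]: boosting is impossible, the baseline wins
  expect_equal(fit$gain, 1, tolerance = 1e-6)
})

test_that("static optimization finds the saturating level on the toy chain", {
  fit <- optimize_static(toy3, cluster = "R1", horizon = 600,
                         constraints = toy_cons, target = "M3",
                         budget = 150, n_starts = 3, seed = 2, dt = 5,
                         final_dt = 1)
  expect_gt(fit$gain, 1)
  expect_lt(max(fit$constraint_report$worst_violation), 1e-6)
})

test_that("results are deterministic given the seed", {
  fit2 <- optimize_dynamic(toy3, cluster = "R1", horizon = 600,
                           constraints = toy_cons, target = "M3",
                           omega_range = c(2 * pi / 600, 2 * pi / 30),
                           budget = 250, n_starts = 4, seed = 5,
                           dt = 5, rtol = 1e-8, final_dt = 1)
  expect_identical(fit2$objective, fit_toy$objective)
  expect_identical(tidy(fit2), tidy(fit_toy))
})

test_that("tidy and glance expose the decision variables and summary", {
  td <- tidy(fit_toy)
  expect_identical(td$enzyme, "R1")
  expect_true(all(c("A", "omega", "phi") %in% names(td)))
  gl <- glance(fit_toy)
  expect_identical(gl$gain, fit_toy$gain)
  expect_true(gl$worst_violation < 1e-6)
  path <- withr::local_tempfile(fileext = ".json")
  write_opt_json(fit_toy, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$gain, fit_toy$gain, tolerance = 1e-12)
})
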
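# Forced simulation, integrals and gain ratios.

test_that("the unforced system stays at its steady state for 8 hours", {
  traj <- simulate_network(ccm, NULL, horizon = 8 * 3600, dt = 60)
  dev <- sweep(as.matrix(traj[, ccm$metabolites]), 2, ccm$steady_state, "/")
  expect_lt(max(abs(dev - 1)), 1e-3)
})

test_that("zero-amplitude programs reproduce the empty program exactly", {
  prog0 <- forcing_program(lapply(c("PFK", "GAPDH", "PK", "PEPC", "RPPK",
                                    "SER", "SYN1", "DAHPS", "G6PDH"),
                                  function(e) {
                                    enzyme_profile(e, "cosine", A = 0,
                                                   omega = 0.01)
                                  }))
  t1 <- simulate_network(ccm, prog0, horizon = 3600, dt = 10)
  t2 <- simulate_network(ccm, NULL, horizon = 3600, dt = 10)
  expect_equal(as.matrix(t1[, ccm$metabolites]),
               as.matrix(t2[, ccm$metabolites]), tolerance = 1e-9)
})

test_that("identical inputs give bit-identical trajectories", {
  prog <- forcing_program(enzyme_profile("GAPDH", "cosine", A = 4,
                                         omega = 0.005, e_min = 1))
  t1 <- simulate_network(ccm, prog, horizon = 3600, dt = 10)
  t2 <- simulate_network(ccm, prog, horizon = 3600, dt = 10)
  expect_identical(as.matrix(t1[, ccm$metabolites]),
                   as.matrix(t2[, ccm$metabolites]))
})

test_that("total_metabolite is the trapezoid time integral", {
  traj <- simulate_network(ccm, NULL, horizon = 100, dt = 1)
  expect_equal(total_metabolite(traj, "pep"),
               ccm$steady_state[["pep"]] * 100, tolerance = 1e-6)
  # closed form: integral of sin^2 over [0, 2pi] is pi
  fake <- tibble::tibble(time = seq(0, 2 * pi, length.out = 20001),
                         y = sin(seq(0, 2 * pi, length.out = 20001))^2)
  attr(fake, "metabolites") <- "y"
  expect_equal(sum(diff(fake$time) *
                     (head(fake$y, -1) + tail(fake$y, -1)) / 2),
               pi, tolerance = 1e-6)
  expect_error(total_metabolite(traj, "atp"), "unknown metabolite",
               class = "oscimet_config_error")
})

test_that("trapezoid totals match an independent Simpson oracle", {
  skip_if_not_installed("pracma")
  prog <- forcing_program(enzyme_profile("GAPDH", "cosine", A = 3,
                                         omega = 2 * pi / 1800, e_min = 1))
  traj <- simulate_network(ccm, prog, horizon = 7200, dt = 1)
  simpson <- pracma::simpadpt(function(tt) {
    stats::approx(traj$time, traj$pep, xout = tt)$y
  }, 0, 7200, tol = 1e-10)
  expect_equal(total_metabolite(traj, "pep"), simpson, tolerance = 1e-6)
})

test_that("total PEP is invariant to reporting-grid refinement", {
  prog <- forcing_program(enzyme_profile("GAPDH", "cosine", A = 2,
                                         omega = 2 * pi / 3600, e_min = 1))
  t1 <- simulate_network(ccm, prog, horizon = 8 * 3600, dt = 2)
  t2 <- simulate_network(ccm, prog, horizon = 8 * 3600, dt = 1)
  expect_equal(total_metabolite(t1, "pep"), total_metabolite(t2, "pep"),
               tolerance = 1e-6)
})

test_that("total PEP is stable under solver-tolerance tightening", {
  prog <- forcing_program(enzyme_profile("GAPDH", "cosine", A = 2,
                                         omega = 2 * pi / 3600, e_min = 1))
  t1 <- simulate_network(ccm, prog, horizon = 8 * 3600, dt = 10, rtol = 1e-6)
  t2 <- simulate_network(ccm, prog, horizon = 8 * 3600, dt = 10, rtol = 1e-10)
  expect_equal(total_metabolite(t1, "pep"), total_metabolite(t2, "pep"),
               tolerance = 1e-4)
})

test_that("compiled and R engines integrate to the same trajectory", {
  prog <- forcing_program(enzyme_profile("PEPC", "cosine", A = 0.8,
                                         omega = 2 * pi / 900, phi = 1))
  tc <- simulate_network(ccm, prog, horizon = 1800, dt = 30,
                         engine = "compiled")
  tr <- simulate_network(ccm, prog, horizon = 1800, dt = 30, engine = "r")
  expect_equal(as.matrix(tc[, ccm$metabolites]),
               as.matrix(tr[, ccm$metabolites]), tolerance = 1e-6)
})

test_that("gain_ratio behaves as a ratio of integrals", {
  base <- simulate_network(ccm, NULL, horizon = 600, dt = 10)
  expect_equal(gain_ratio(base, base), 1)
  doubled <- base
  doubled$pep <- 2 * base$pep
  expect_equal(gain_ratio(doubled, base), 2)
  short <- simulate_network(ccm, NULL, horizon = 300, dt = 10)
  expect_error(gain_ratio(short, base), "horizon",
               class = "oscimet_config_error")
})

test_that("trajectories tidy and export with units header", {
  traj <- simulate_network(ccm, NULL, horizon = 60, dt = 30)
  long <- tidy(traj, include_enzymes = TRUE)
  expect_setequal(unique(long$kind), c("metabolite", "enzyme"))
  expect_equal(nrow(long), 3 * (18 + 32))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  expect_match(readLines(path, n = 1), "mM")
})
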
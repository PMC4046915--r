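# Waveform profiles and forcing programs.

test_that("profile evaluation matches the closed forms", {
  expect_equal(eval_profile(enzyme_profile("PFK", "cosine", A = 0), 13.7), 1)
  expect_equal(eval_profile(enzyme_profile("PFK", "cosine", A = 2,
                                           omega = 0.01, e_min = 0.05), 0), 3)
  sq <- enzyme_profile("PFK", "square", A = 0.5, omega = 2 * pi / 100)
  expect_equal(eval_profile(sq, 10), 1.5)   # cos > 0
  expect_equal(eval_profile(sq, 40), 0.5)   # cos < 0
  inv <- enzyme_profile("PEPC", "cosine", A = 0.5, omega = 1,
                        inverted = TRUE)
  expect_equal(eval_profile(inv, 0), 0.5)
  const <- enzyme_profile("PK", "constant", h = 100, A = 3, omega = 1)
  expect_equal(eval_profile(const, c(0, 5, 50)), c(100, 100, 100))
})

test_that("a large-amplitude cosine is rectified exactly to its bounds", {
  p <- enzyme_profile("GAPDH", "cosine", A = 19, omega = 2 * pi / 600,
                      phi = 0, e_min = 0.05, e_max = 20)
  lv <- eval_profile(p, seq(0, 600, by = 0.01))
  expect_equal(min(lv), 0.05)
  expect_equal(max(lv), 20)
})

test_that("periodic waveforms are periodic and clamp-contained", {
  set.seed(21)
  for (i in 1:50) {
    p <- enzyme_profile("PFK", sample(c("cosine", "square"), 1),
                        A = runif(1, 0, 30), omega = runif(1, 1e-4, 0.1),
                        phi = runif(1, 0, 2 * pi), e_min = runif(1, 0.01, 0.5),
                        e_max = runif(1, 2, 25),
                        inverted = sample(c(TRUE, FALSE), 1))
    t <- runif(20, 0, 1e5)
    lv <- eval_profile(p, t)
    expect_true(all(lv >= p$e_min - 1e-12 & lv <= p$e_max + 1e-12))
    expect_equal(eval_profile(p, t + 2 * pi / p$omega), lv, tolerance = 1e-8)
  }
})

test_that("phase is stored modulo 2 pi", {
  p <- enzyme_profile("PFK", "cosine", A = 1, omega = 1, phi = 7 * pi)
  expect_equal(p$phi, pi)
})

test_that("programs reject duplicates and unknown enzymes", {
  expect_error(forcing_program(enzyme_profile("PFK", "cosine"),
                               enzyme_profile("PFK", "square")),
               "duplicate", class = "oscimet_config_error")
  prog <- forcing_program(enzyme_profile("NOPE", "cosine", A = 1))
  expect_error(simulate_network(ccm, prog, horizon = 10, dt = 5),
               "NOPE", class = "oscimet_config_error")
})

test_that("circuit programs are anti-phase with floored induced members", {
  amps <- c(GAPDH = 5, PFK = 4, RPPK = 0.9)
  prog <- circuit_program(2 * pi / 3600, 0.4, amps)
  t <- seq(0, 8 * 3600, by = 10)
  g <- eval_profile(prog$GAPDH, t)
  r <- eval_profile(prog$RPPK, t)
  expect_gte(min(g), 1)                      # plasmid floor
  expect_equal(which.max(g), which.min(r))   # anti-phase by construction
  # zero amplitudes give the constant unforced baseline
  prog0 <- circuit_program(2 * pi / 3600, 0.4,
                           c(GAPDH = 0, PFK = 0, RPPK = 0))
  for (p in prog0) expect_equal(eval_profile(p, t), rep(1, length(t)))
  expect_error(circuit_program(1, 0, amps,
                               members = list(induced = character(),
                                              repressed = character())),
               class = "oscimet_config_error")
})

test_that("programs serialize to plain lists and back", {
  prog <- forcing_program(
    enzyme_profile("GAPDH", "cosine", A = 3, omega = 0.01, phi = 1,
                   e_min = 1),
    enzyme_profile("RPPK", "square", A = 0.5, omega = 0.002, inverted = TRUE))
  rt <- oscimet:::program_from_list(oscimet:::program_to_list(prog))
  expect_equal(rt, prog)
})
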
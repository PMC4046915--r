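# Core network model: rate laws, right-hand side, parameter file.

oracle_rates <- c(
  PTS = 0.2002505319641194,
  PGI = 0.0583964392180771,
  PGM = 0.0023333300266379863,
  G6PDH = 0.13942401877933763,
  PFK = 0.14325319277257373,
  TA = 0.045313053149713,
  TKA = 0.045320725952526,
  TKB = 0.0384320955491035,
  MURSYNTH = 0.00043711,
  ALDO = 0.14124312636148006,
  GAPDH = 0.3202894194118623,
  TIS = 0.1395755850832006,
  TRPSYNTH = 0.001037,
  G3PDH = 0.0016628986895289022,
  PGK = 0.3202891970124647,
  SER = 0.017499912029976254,
  PGLUMU = 0.3027300433430569,
  ENO = 0.3027189511731225,
  PK = 0.040115492492186905,
  PEPC = 0.04318796170706645,
  SYN1 = 0.014215011323362977,
  SYN2 = 0.05355903572493645,
  DAHPS = 0.0068782332062317176,
  PDH = 0.18802995741348968,
  METSYNTH = 0.0022627,
  PGDH = 0.13940157029699063,
  R5PI = 0.055641826600717606,
  RU5P = 0.08375665789816283,
  RPPK = 0.010310036258315402,
  G1PAT = 0.0023151905349367346,
  PPS = 0.0020025053191129517,
  FBP = 0.002002504845391586)

test_that("nominal rates match an independently coded oracle", {
  r <- rate_vector(ccm, ccm$steady_state)
  expect_equal(r[names(oracle_rates)], oracle_rates, tolerance = 1e-9)
})

test_that("network dimensions and stoichiometric consistency hold", {
  expect_length(ccm$metabolites, 18)
  expect_length(ccm$reactions, 32)
  expect_identical(dim(ccm$S), c(18L, 32L))
  expect_true(all(c("PPS", "FBP") %in% ccm$reactions))
  rmax <- vapply(ccm$params, function(p) p[["rmax"]], numeric(1))
  expect_true(all(rmax > 0))
})

test_that("rates are linear in the enzyme level and vanish at level zero", {
  C <- ccm$steady_state
  expect_equal(unname(rate_vector(ccm, C, rep(0, 32))), rep(0, 32))
  r1 <- rate_vector(ccm, C)
  for (alpha in c(0.25, 2, 7.5)) {
    e <- setNames(alpha, "GAPDH")
    r <- rate_vector(ccm, C, e)
    expect_equal(r[["GAPDH"]], alpha * r1[["GAPDH"]])
    expect_equal(r[setdiff(names(r1), "GAPDH")],
                 r1[setdiff(names(r1), "GAPDH")])
  }
})

test_that("rhs equals S r + F - mu C (matrix-product oracle, toy chain)", {
  set.seed(11)
  for (i in 1:100) {
    C <- toy_branched$steady_state * exp(runif(4, -2, 2))
    expected <- drop(toy_branched$S %*% rate_vector(toy_branched, C)) +
      toy_branched$feed - toy_branched$mu * C
    expect_equal(network_rhs(toy_branched, 0, C), expected)
  }
})

test_that("all-zero enzyme levels leave only feed and dilution", {
  C <- ccm$steady_state
  d <- network_rhs(ccm, 0, C, rep(0, 32))
  expect_equal(unname(d), unname(ccm$feed - ccm$mu * C))
})

test_that("no rate law returns NaN for positive states within 100x nominal", {
  set.seed(5)
  for (i in 1:50) {
    C <- ccm$steady_state * exp(runif(18, log(1 / 100), log(100)))
    expect_true(all(is.finite(rate_vector(ccm, C))))
  }
})

test_that("bad inputs raise typed errors naming the offender", {
  expect_error(rate_vector(ccm, ccm$steady_state - 5),
               "negative concentration", class = "oscimet_numeric_error")
  expect_error(rate_vector(ccm, ccm$steady_state, c(NOSUCH = 1)),
               "NOSUCH", class = "oscimet_config_error")
  bad <- ccm$steady_state
  names(bad)[1] <- "glucose_x"
  expect_error(rate_vector(ccm, bad), "glucose_x",
               class = "oscimet_config_error")
})

test_that("parameter file round-trips bit-exactly", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_network(ccm, path)
  net2 <- load_network(path)
  expect_identical(net2$params, ccm$params)
  expect_identical(net2$steady_state, ccm$steady_state)
  expect_identical(net2$S, ccm$S)
  expect_identical(net2$mu, ccm$mu)
  expect_identical(net2$cometabolites, ccm$cometabolites)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_network(net2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("rebuilding from source constants reproduces the shipped file", {
  rebuilt <- build_ccm_network()
  expect_equal(rebuilt$params, ccm$params, tolerance = 1e-12)
  expect_equal(rebuilt$steady_state, ccm$steady_state, tolerance = 1e-9)
  expect_equal(rebuilt$pts_scale, ccm$pts_scale, tolerance = 1e-12)
})

test_that("compiled and R right-hand sides agree under forcing", {
  prog <- forcing_program(
    enzyme_profile("GAPDH", "cosine", A = 5, omega = 2 * pi / 3600,
                   phi = 0.3, e_min = 1),
    enzyme_profile("PEPC", "square", A = 0.9, omega = 2 * pi / 7200, phi = 2),
    enzyme_profile("PK", "constant", h = 0.4))
  pv <- oscimet:::ccm_parms_vector(ccm, prog)
  efn <- program_level_fn(ccm, prog)
  set.seed(3)
  for (i in 1:25) {
    C <- ccm$steady_state * exp(runif(18, -1.5, 1.5))
    t <- runif(1, 0, 28800)
    d_c <- deSolve::DLLfunc(func = "oscimet_derivs", dllname = "oscimet",
                            initfunc = "oscimet_initmod", times = t,
                            y = unname(C), parms = pv)$dy
    d_r <- unname(network_rhs(ccm, t, C, efn(t)))
    expect_equal(d_c, d_r, tolerance = 1e-12)
  }
})
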
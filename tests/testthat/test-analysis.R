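# Pearson correlation of trajectory series.

two_pass_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

prog <- forcing_program(
  enzyme_profile("GAPDH", "cosine", A = 0.9, omega = 2 * pi / 1800),
  enzyme_profile("PEPC", "cosine", A = 0.9, omega = 2 * pi / 1800,
                 phi = pi))
traj <- simulate_network(ccm, prog, horizon = 3600, dt = 10)

test_that("self and mirrored series give +1 and -1", {
  cm <- correlate_trajectory(traj, c("pep", "GAPDH", "PEPC"))
  expect_equal(diag(unclass(cm)), c(pep = 1, GAPDH = 1, PEPC = 1))
  # GAPDH and PEPC waves are exact mirrors of each other
  expect_equal(cm["GAPDH", "PEPC"], -1, tolerance = 1e-12)
})

test_that("coefficients match a textbook two-pass oracle", {
  cm <- correlate_trajectory(traj)
  X <- attr(cm, "series")
  set.seed(9)
  for (k in 1:20) {
    ij <- sample(ncol(X), 2)
    a <- X[, ij[1]]; b <- X[, ij[2]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    expect_equal(cm[ij[1], ij[2]], two_pass_pearson(a, b),
                 tolerance = 1e-12)
  }
  expect_true(all(abs(cm[!is.na(cm)]) <= 1 + 1e-12))
  expect_equal(unclass(cm)[lower.tri(cm)],
               t(unclass(cm))[lower.tri(cm)])
})

test_that("correlation is invariant under affine rescaling", {
  x <- traj$pep
  y <- traj$g6p
  expect_equal(two_pass_pearson(3.7 * x - 11, y),
               two_pass_pearson(x, y), tolerance = 1e-12)
  expect_equal(two_pass_pearson(x, -2 * y + 5),
               -two_pass_pearson(x, y), tolerance = 1e-12)
})

test_that("constant series get an undefined sentinel, not NaN", {
  cm <- correlate_trajectory(traj, c("pep", "PK"))   # PK is unforced
  expect_true(is.na(cm["pep", "PK"]))
  expect_false(any(is.nan(unclass(cm))))
})

test_that("unknown variables and degenerate grids error", {
  expect_error(correlate_trajectory(traj, c("pep", "bogus")), "bogus",
               class = "oscimet_config_error")
  expect_error(correlate_trajectory(traj[1, ]),
               class = "oscimet_config_error")
})

test_that("tidy and CSV export carry the labels", {
  cm <- correlate_trajectory(traj, c("pep", "pyr", "GAPDH"))
  td <- tidy(cm)
  expect_identical(nrow(td), 9L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cor_csv(cm, path)
  got <- utils::read.csv(path, row.names = 1)
  expect_identical(rownames(got), c("pep", "pyr", "GAPDH"))
})
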
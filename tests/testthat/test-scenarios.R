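# Knockout / overexpression scenarios and the pair screen.

test_that("essential enzymes are refused for knockout", {
  expect_error(knockout(ccm, "RPPK"), "RPPK",
               class = "oscimet_config_error")
  expect_error(knockout(ccm, "NOSUCH"), class = "oscimet_config_error")
})

test_that("a unit overexpression is the baseline", {
  expect_equal(overexpress(ccm, "GAPDH", fold = 1, horizon = 1800,
                           dt = 60), 1, tolerance = 1e-9)
})

test_that("overexpression at fold zero equals the knockout", {
  g_ko <- knockout(ccm, "PEPC", horizon = 1800, dt = 60)
  g_ov <- suppressWarnings(overexpress(ccm, "PEPC", fold = 0,
                                       horizon = 1800, dt = 60))
  expect_equal(g_ko, g_ov, tolerance = 1e-10)
})

test_that("knocking out a dead branch changes nothing", {
  net <- make_toy_network(4, branch = TRUE, seed = 7, branch_vmax = 0)
  g <- knockout(net, "B", horizon = 600, target = "M4", dt = 5)
  expect_equal(g, 1, tolerance = 1e-9)
})

test_that("GAPDH overexpression raises total PEP", {
  expect_gt(suppressWarnings(overexpress(ccm, "GAPDH", fold = 100,
                                         horizon = 3600, dt = 60)), 1)
})

test_that("scenario simulations warn when physiological bands are left", {
  expect_warning(overexpress(ccm, "GAPDH", fold = 100, horizon = 3600,
                             dt = 60), "physiological")
})

test_that("intervention tables cover knockouts and overexpressions", {
  tab <- suppressWarnings(
    intervention_table(ccm, enzymes = c("PEPC", "RPPK"), fold = 100,
                       horizon = 1800))
  expect_identical(nrow(tab), 3L)   # RPPK essential: no knockout row
  expect_setequal(unique(tab$intervention),
                  c("knockout", "overexpress_100x"))
})

test_that("the pair screen ranks deterministically and beats its singles", {
  cands <- c("GAPDH", "PEPC", "PFK")
  pairs <- pair_screen(ccm, cands, budget = 150, n_starts = 3, seed = 4)
  expect_identical(nrow(pairs), 3L)
  expect_true(all(diff(pairs$gain) <= 1e-12))
  pairs2 <- pair_screen(ccm, cands, budget = 150, n_starts = 3, seed = 4)
  expect_identical(pairs$gain, pairs2$gain)
  singles <- vapply(cands, function(e) {
    optimize_dynamic(ccm, e, budget = 150, n_starts = 3, seed = 4)$gain
  }, numeric(1))
  for (k in seq_len(nrow(pairs))) {
    best_single <- max(singles[[pairs$enzyme_a[k]]],
                       singles[[pairs$enzyme_b[k]]])
    expect_gte(pairs$gain[k], best_single - 0.02)
  }
})
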
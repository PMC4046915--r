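# Knockout / overexpression scenarios and the two-enzyme combination screen.

scenario_gain <- function(net, level, enzyme, horizon, target, dt, rtol) {
  program <- constant_program(net, setNames(level, enzyme))
  traj <- simulate_network(net, program, horizon = horizon, dt = dt,
                           rtol = rtol, atol = 1e-10)
  base <- simulate_network(net, NULL, horizon = horizon, dt = dt,
                           rtol = rtol, atol = 1e-10)
  viol <- worst_violations(traj, default_path_constraints(net))
  if (any(viol > 1e-6)) {
    bad <- names(viol)[viol > 1e-6]
    warn(paste0("scenario leaves the physiological range of: ",
                paste0(bad, " (by ", format(signif(viol[bad], 3)),
                       " mM)", collapse = ", ")))
  }
  gain_ratio(traj, base, target)
}

#' Simulated gene knockout
#'
#' Sets one enzyme's level to zero for the whole horizon (starting from the
#' nominal steady state) and reports the gain in time-integrated target
#' metabolite relative to the unperturbed system.  Knockouts of
#' growth-essential enzymes are refused.  Trajectories that leave the
#' default physiological ranges are still simulated, with a warning listing
#' the violated bands.
#'
#' @param net a [metabolic_network()].
#' @param enzyme reaction to delete.
#' @param horizon seconds (default 8 h).
#' @param target metabolite (default `"pep"`).
#' @param dt,rtol simulation settings.
#' @return Dimensionless gain ratio.
#' @export
knockout <- function(net, enzyme, horizon = 8 * HOUR, target = "pep",
                     dt = 30, rtol = 1e-8) {
  if (!enzyme %in% net$reactions) {
    abort_config(paste0("unknown reaction '", enzyme, "'"))
  }
  if (enzyme %in% net$essential) {
    abort_config(paste0("refusing to knock out '", enzyme,
                        "': essential for cellular viability"))
  }
  scenario_gain(net, 0, enzyme, horizon, target, dt, rtol)
}

#' Simulated constitutive overexpression
#'
#' Holds one enzyme at `fold` times its nominal level for the whole horizon.
#'
#' @inheritParams knockout
#' @param fold constant enzyme level (default 100).
#' @return Dimensionless gain ratio.
#' @export
overexpress <- function(net, enzyme, fold = 100, horizon = 8 * HOUR,
                        target = "pep", dt = 30, rtol = 1e-8) {
  if (!enzyme %in% net$reactions) {
    abort_config(paste0("unknown reaction '", enzyme, "'"))
  }
  if (fold < 0) abort_config("fold must be non-negative")
  scenario_gain(net, fold, enzyme, horizon, target, dt, rtol)
}

#' Two-enzyme oscillation combination screen
#'
#' Runs a reduced-budget [optimize_dynamic()] for every unordered pair of
#' candidate enzymes and ranks the pairs by achieved gain (descending, ties
#' alphabetical).
#'
#' @param net a [metabolic_network()].
#' @param candidates enzymes to combine (e.g. the flagged set of
#'   [sensitivity_screen()]).
#' @param budget objective evaluations per pair.
#' @param n_starts local searches per pair.
#' @param seed integer seed.
#' @param ... forwarded to [optimize_dynamic()].
#' @return Tibble with columns `enzyme_a`, `enzyme_b`, `gain`, ordered by
#'   rank; the per-pair `pep_opt` objects are attached as attribute
#'   `"results"`.
#' @export
pair_screen <- function(net, candidates, budget = 200, n_starts = 3,
                        seed = 1, ...) {
  check_cluster(net, candidates)
  if (length(candidates) < 2) abort_config("need at least two candidates")
  pairs <- utils::combn(sort(candidates), 2)
  fits <- lapply(seq_len(ncol(pairs)), function(k) {
    optimize_dynamic(net, cluster = pairs[, k], budget = budget,
                     n_starts = n_starts, seed = seed + k, ...)
  })
  out <- tibble::tibble(
    enzyme_a = pairs[1, ], enzyme_b = pairs[2, ],
    gain = vapply(fits, function(f) f$gain, numeric(1)))
  ord <- order(-out$gain, out$enzyme_a, out$enzyme_b)
  out <- out[ord, ]
  attr(out, "results") <- fits[ord]
  out
}

#' Table of single-gene intervention gains
#'
#' Knockout (non-essential enzymes) and overexpression gains for a set of
#' enzymes, as a tidy table.
#'
#' @inheritParams knockout
#' @param enzymes enzymes to perturb (default: all).
#' @param fold overexpression level (default 100).
#' @return Tibble with columns `enzyme`, `intervention`, `gain`.
#' @export
intervention_table <- function(net, enzymes = net$reactions, fold = 100,
                               horizon = 8 * HOUR, target = "pep") {
  rows <- list()
  for (rx in enzymes) {
    if (!rx %in% net$essential) {
      g <- tryCatch(suppressWarnings(knockout(net, rx, horizon, target)),
                    error = function(e) NA_real_)
      rows[[length(rows) + 1]] <-
        tibble::tibble(enzyme = rx, intervention = "knockout", gain = g)
    }
    g <- tryCatch(suppressWarnings(overexpress(net, rx, fold, horizon,
                                               target)),
                  error = function(e) NA_real_)
    rows[[length(rows) + 1]] <-
      tibble::tibble(enzyme = rx,
                     intervention = paste0("overexpress_", fold, "x"),
                     gain = g)
  }
  dplyr::bind_rows(rows)
}
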
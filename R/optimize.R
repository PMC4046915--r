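# Dynamic (waveform) and time-invariant (constant-level) optimization of
# enzyme programs maximizing the time integral of a target metabolite under
# metabolite path constraints.
#
# Single shooting: every candidate decision vector becomes a forcing
# program, the forced ODE system is simulated, and the objective is the
# trapezoid integral of the target minus an exact penalty on path-constraint
# violations.  The clamped waveforms make the landscape only piecewise
# smooth and the optimum rides the constraint boundary, so the search is
# gradient-free and feasibility-aware: a deterministic amplitude line
# search along structured "push" rays, seeded Latin-hypercube starts, a
# Nelder-Mead polish of each, selection of the best feasible point over the
# whole evaluation history, and a final amplitude backtrack verified at
# fine solver settings.

worst_violations <- function(traj, constraints) {
  vapply(names(constraints), function(m) {
    y <- traj[[m]]
    b <- constraints[[m]]
    max(0, b[1] - min(y), max(y) - b[2])
  }, numeric(1))
}

# quick probe: does a constant 50% increase of `enzyme` raise or lower the
# target?  Used to aim the structured start rays.
probe_direction <- function(net, enzyme, target = "pep", horizon = HOUR) {
  base <- net$steady_state[[target]] * horizon
  traj <- simulate_network(net, constant_program(net, setNames(1.5, enzyme)),
                           horizon = horizon, dt = 60, rtol = 1e-6,
                           atol = 1e-9)
  sign(total_metabolite(traj, target) - base)
}

check_cluster <- function(net, cluster) {
  if (!length(cluster)) abort_config("cluster must be non-empty")
  bad <- setdiff(cluster, net$reactions)
  if (length(bad)) {
    abort_config(paste0("cluster names unknown reaction(s): ",
                        paste(bad, collapse = ", ")))
  }
}

om01 <- function(omega, omega_range) {
  min(1, max(0, (omega - omega_range[1]) / diff(omega_range)))
}

lhs_starts <- function(n, d, seed) {
  if (n <= 0) return(list())
  set.seed(seed)
  Z <- lhs::randomLHS(n, d)
  lapply(seq_len(n), function(i) Z[i, ])
}

# Shared search engine ------------------------------------------------------

run_search <- function(net, decode, d, backtrack, starts, budget, seed,
                       horizon, dt, rtol, constraints, penalty, target,
                       final_dt, final_rtol, feas_tol = 1e-6,
                       groups = NULL) {
  rec <- new.env(parent = emptyenv())
  rec$Z <- list()
  rec$raw <- numeric(0)
  rec$viol <- numeric(0)
  evaluate <- function(z) {
    traj <- tryCatch(
      simulate_network(net, decode(z), horizon = horizon, dt = dt,
                       rtol = rtol, atol = 1e-9),
      error = function(e) NULL)
    if (is.null(traj)) {
      rec$Z[[length(rec$Z) + 1]] <- z
      rec$raw <- c(rec$raw, -Inf)
      rec$viol <- c(rec$viol, Inf)
      return(-1e10)
    }
    raw <- total_metabolite(traj, target)
    v <- sum(worst_violations(traj, constraints))
    rec$Z[[length(rec$Z) + 1]] <- z
    rec$raw <- c(rec$raw, raw)
    rec$viol <- c(rec$viol, v)
    raw - penalty * v
  }
  counted <- function(z) {
    zc <- pmin(pmax(z, 0), 1)
    -evaluate(zc) + 1e5 * sum(pmax(0, z - 1, -z))
  }
  polish <- function(z0, maxit) {
    if (d == 1) {
      optim(z0, counted, method = "Brent", lower = 0, upper = 1)
    } else {
      optim(z0, counted, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = 1e-9))
    }
  }

  set.seed(seed)
  # phase 1: screen every start with a single evaluation
  screened <- vapply(starts, function(z) evaluate(pmin(pmax(z, 0), 1)),
                     numeric(1))
  # phase 2: deep Nelder-Mead polish of the best screened starts; when the
  # caller labels start families (e.g. one per trial period), polish the
  # best start of each family so distinct basins all get explored
  if (is.null(groups)) {
    n_polish <- min(5L, length(starts))
    top <- order(-screened)[seq_len(n_polish)]
  } else {
    top <- vapply(split(seq_along(starts), groups), function(idx) {
      idx[which.max(screened[idx])]
    }, integer(1))
    top <- top[order(-screened[top])]
    n_polish <- length(top)
  }
  history <- numeric(0)
  for (i in top) {
    if (length(rec$raw) >= budget) break
    maxit <- max(50, floor((budget - length(rec$raw)) / n_polish))
    fit <- tryCatch(polish(starts[[i]], maxit), error = function(e) NULL)
    if (!is.null(fit)) history <- c(history, -fit$value)
  }
  # phase 3: restart polishing while budget remains (a fresh simplex
  # escapes the collapsed one of a converged run), alternating between the
  # best penalized incumbent and the best strictly feasible one
  for (restart in seq_len(8)) {
    left <- budget - length(rec$raw)
    if (left < 50) break
    pen <- rec$raw - penalty * rec$viol
    prev <- max(pen)
    zb <- if (restart %% 2 == 0 && any(rec$viol <= 1e-9)) {
      ok <- which(rec$viol <= 1e-9)
      rec$Z[[ok[which.max(rec$raw[ok])]]]
    } else {
      rec$Z[[which.max(pen)]]
    }
    fit <- tryCatch(polish(zb, left), error = function(e) NULL)
    if (is.null(fit)) break
    history <- c(history, -fit$value)
    if (-fit$value <= prev + 1e-4 * abs(prev)) break
  }
  n_eval <- length(rec$raw)

  fine_check <- function(z) {
    traj <- tryCatch(
      simulate_network(net, decode(z), horizon = horizon, dt = final_dt,
                       rtol = final_rtol, atol = 1e-11),
      error = function(e) NULL)
    if (is.null(traj)) return(NULL)
    list(z = z, traj = traj, raw = total_metabolite(traj, target),
         viol = max(worst_violations(traj, constraints)))
  }

  # Candidate selection: the best coarse-feasible points plus the best
  # penalized ones, each verified at fine settings (coarse-grid maxima can
  # miss constraint peaks between reporting points) and, when marginally
  # infeasible there, backed off towards the feasible region (amplitudes
  # towards zero, or constant levels towards one).  Keep the best feasible
  # objective across all candidates.
  pen <- rec$raw - penalty * rec$viol
  feas <- which(rec$viol <= 1e-9)
  cand <- unique(c(head(feas[order(-rec$raw[feas])], 10),
                   head(order(-pen), 3)))
  chosen <- NULL
  for (i in cand) {
    for (alpha in c(1, 0.99, 0.98, 0.96, 0.94, 0.9, 0.85, 0.8)) {
      fc <- fine_check(backtrack(rec$Z[[i]], alpha))
      if (!is.null(fc) && fc$viol <= feas_tol) {
        if (is.null(chosen) || fc$raw > chosen$raw) chosen <- fc
        break
      }
    }
  }
  if (is.null(chosen) && length(rec$raw)) {
    zb <- rec$Z[[which.max(pen)]]
    for (alpha in seq(0.75, 0, by = -0.05)) {
      fc <- fine_check(backtrack(zb, alpha))
      if (!is.null(fc) && fc$viol <= feas_tol) {
        chosen <- fc
        break
      }
    }
  }
  list(chosen = chosen, history = history, n_eval = n_eval)
}

finish_optimization <- function(net, decode, search, horizon, constraints,
                                target, seed, final_dt, final_rtol,
                                feas_tol = 1e-6) {
  base <- simulate_network(net, NULL, horizon = horizon, dt = final_dt,
                           rtol = final_rtol, atol = 1e-11)
  base_obj <- total_metabolite(base, target)
  base_viol <- worst_violations(base, constraints)
  chosen <- search$chosen
  converged <- !is.null(chosen)
  # never report a forced optimum that is worse than the (feasible)
  # baseline, which is always an admissible program
  if ((is.null(chosen) || chosen$raw < base_obj) &&
      max(base_viol) <= feas_tol) {
    chosen <- list(z = NULL, traj = base, raw = base_obj,
                   viol = max(base_viol))
    converged <- TRUE
  }
  if (is.null(chosen)) {
    abort_numeric("no feasible program found and the baseline is infeasible")
  }
  program <- if (is.null(chosen$z)) forcing_program(list()) else
    decode(chosen$z)
  viol <- worst_violations(chosen$traj, constraints)
  structure(list(
    program = program,
    objective = chosen$raw,
    baseline_objective = base_obj,
    gain = chosen$raw / base_obj,
    constraint_report = tibble::tibble(
      metabolite = names(viol),
      lo = vapply(constraints, `[`, numeric(1), 1),
      hi = vapply(constraints, `[`, numeric(1), 2),
      worst_violation = unname(viol)),
    converged = converged && max(viol) <= feas_tol,
    starts = search$history,
    n_eval = search$n_eval,
    seed = seed,
    target = target,
    horizon = horizon,
    trajectory = chosen$traj,
    baseline_trajectory = base), class = "pep_opt")
}

#' Dynamic optimization of periodic enzyme programs
#'
#' Maximizes the time integral of the target metabolite over `horizon` by
#' tuning amplitude, frequency and phase of one wave per cluster enzyme,
#' subject to metabolite path constraints enforced through an exact penalty
#' during the search; the reported optimum is feasible (within `1e-6` mM)
#' at fine solver settings.  Enzymes in `floor_enzymes` (plasmid-supplied
#' producers) keep a lower level bound of 1; all waves are clamped to
#' `[e_min, e_max]`.
#'
#' @param net a [metabolic_network()].
#' @param cluster enzymes to force (non-empty subset of the reactions).
#' @param horizon seconds (default 8 h).
#' @param waveform `"cosine"` or `"square"`.
#' @param constraints named list of `c(lo, hi)` path bounds, mM
#'   (default [default_path_constraints()]).
#' @param floor_enzymes enzymes whose level may not drop below 1.
#' @param e_min,e_max waveform clamp bounds.
#' @param A_max amplitude search ceiling (amplitudes beyond the clamp span
#'   flatten the wave towards a square).
#' @param omega_range angular-frequency search range, rad/s; the default
#'   spans oscillation periods from 5 minutes to the full horizon.
#' @param n_starts number of Nelder-Mead starts (structured rays +
#'   Latin hypercube).
#' @param budget total objective-evaluation budget.
#' @param seed integer; all randomness (start placement) derives from it.
#' @param dt,rtol reporting grid and solver tolerance used during the
#'   search; the reported optimum is re-simulated at `final_dt`,
#'   `final_rtol`.
#' @param penalty exact-penalty weight, mM.s per mM of summed worst
#'   violations.
#' @param target objective metabolite.
#' @param final_dt,final_rtol settings of the reported re-simulation.
#' @return A `pep_opt` object; see [tidy.pep_opt()] and [glance.pep_opt()].
#' @export
optimize_dynamic <- function(net, cluster, horizon = 8 * HOUR,
                             waveform = c("cosine", "square"),
                             constraints = default_path_constraints(net),
                             floor_enzymes = c("GAPDH", "PFK"),
                             e_min = 1 / 20, e_max = 20, A_max = 40,
                             omega_range = c(2 * pi / horizon, 2 * pi / 300),
                             n_starts = 10, budget = 2000, seed = 1,
                             dt = 60, rtol = 1e-6, penalty = 1e4,
                             target = "pep", final_dt = 5,
                             final_rtol = 1e-8) {
  waveform <- match.arg(waveform)
  check_cluster(net, cluster)
  m <- length(cluster)
  d <- 3L * m
  floors <- ifelse(cluster %in% floor_enzymes, 1, e_min)

  decode <- function(z) {
    A <- z[seq_len(m)] * A_max
    omega <- omega_range[1] + z[m + seq_len(m)] * diff(omega_range)
    phi <- z[2 * m + seq_len(m)] * 2 * pi
    forcing_program(lapply(seq_len(m), function(i) {
      enzyme_profile(cluster[i], waveform, A = A[i], omega = omega[i],
                     phi = phi[i], e_min = floors[i], e_max = e_max)
    }))
  }

  dirs <- vapply(cluster, probe_direction, numeric(1), net = net,
                 target = target)
  # synchronized push ray: producers crest (phase 0) while the
  # production-decreasing enzymes trough (phase pi); amplitude scales with
  # s, capped near the symmetric range for the troughing enzymes so their
  # levels do not swing far above 1 in the off half-cycle
  ray <- function(s, period) {
    A01 <- ifelse(dirs >= 0, s * 19, pmin(0.95, s * 1.9)) / A_max
    c(A01, rep(om01(2 * pi / period, omega_range), m),
      ifelse(dirs >= 0, 0, 0.5))
  }
  periods <- c(600, 1800, 3600, 14400, horizon)
  svals <- c(0.05, 0.08, 0.11, 0.14, 0.17, 0.2, 0.25, 0.35, 0.5, 0.75, 1)
  ray_starts <- unlist(lapply(periods, function(p) {
    lapply(svals, function(s) ray(s, p))
  }), recursive = FALSE)
  rnd <- lhs_starts(max(0, n_starts - 4), d, seed)
  # for low-dimensional problems a full three-level factorial is affordable
  # and covers the box better than rays
  fact <- if (d <= 3) {
    g <- as.matrix(expand.grid(rep(list(c(0, 0.5, 1)), d)))
    lapply(seq_len(nrow(g)), function(i) unname(g[i, ]))
  } else list()
  starts <- c(list(rep(0, d)), ray_starts, fact, rnd)
  groups <- c("base", rep(paste0("T", periods), each = length(svals)),
              rep("grid", length(fact)), rep("lhs", length(rnd)))

  backtrack <- function(z, alpha) {
    z[seq_len(m)] <- alpha * z[seq_len(m)]
    z
  }
  search <- run_search(net, decode, d, backtrack, starts, budget,
                       seed, horizon, dt, rtol, constraints, penalty,
                       target, final_dt, final_rtol, groups = groups)
  finish_optimization(net, decode, search, horizon, constraints, target,
                      seed, final_dt, final_rtol)
}

#' Time-invariant (constant-level) optimization
#'
#' The control counterpart of [optimize_dynamic()]: enzyme levels are
#' optimized as constants.  Levels may vary in `[0, 20]`, except
#' growth-essential enzymes, restricted to `[0.25, 20]`.
#'
#' @inheritParams optimize_dynamic
#' @param h_max upper level bound.
#' @return A `pep_opt` object.
#' @export
optimize_static <- function(net, cluster, horizon = 8 * HOUR,
                            constraints = default_path_constraints(net),
                            h_max = 20, n_starts = 10, budget = 1000,
                            seed = 1, dt = 60, rtol = 1e-6, penalty = 1e4,
                            target = "pep", final_dt = 5,
                            final_rtol = 1e-8) {
  check_cluster(net, cluster)
  m <- length(cluster)
  lo <- ifelse(cluster %in% net$essential, 0.25, 0)

  decode <- function(z) {
    h <- lo + z[seq_len(m)] * (h_max - lo)
    forcing_program(lapply(seq_len(m), function(i) {
      enzyme_profile(cluster[i], "constant", h = h[i])
    }))
  }
  dirs <- vapply(cluster, probe_direction, numeric(1), net = net,
                 target = target)
  base_z <- (1 - lo) / (h_max - lo)            # all levels at 1
  ray <- function(s) {
    h <- ifelse(dirs >= 0, 1 + s * (h_max - 1), 1 + s * (lo - 1))
    (h - lo) / (h_max - lo)
  }
  starts <- c(list(base_z),
              lapply(c(0.05, 0.1, 0.2, 0.35, 0.5, 0.75, 1), ray),
              lhs_starts(max(0, n_starts - 4), m, seed))
  # constant levels have no amplitude; backtracking interpolates the levels
  # towards the all-ones baseline point instead
  backtrack <- function(z, alpha) base_z + alpha * (z - base_z)
  search <- run_search(net, decode, m, backtrack, starts, budget,
                       seed, horizon, dt, rtol, constraints, penalty,
                       target, final_dt, final_rtol)
  finish_optimization(net, decode, search, horizon, constraints, target,
                      seed, final_dt, final_rtol)
}

#' Optimization of the coupled light-circuit program
#'
#' Optimizes the anti-phase program of a single-input switch in which the
#' induced members (default GAPDH, PFK) and the repressed member (default
#' RPPK) share one frequency and phase (`coupling = "circuit"`), or lets
#' every member run its own wave (`coupling = "independent"`) while keeping
#' the induced floors and the repressed inversion.
#'
#' @inheritParams optimize_dynamic
#' @param members list with `induced` and `repressed` character vectors.
#' @param coupling `"circuit"` (shared frequency/phase) or `"independent"`.
#' @return A `pep_opt` object.
#' @export
optimize_circuit <- function(net,
                             members = list(induced = c("GAPDH", "PFK"),
                                            repressed = "RPPK"),
                             coupling = c("circuit", "independent"),
                             horizon = 8 * HOUR,
                             waveform = c("cosine", "square"),
                             constraints = default_path_constraints(net),
                             e_max = 20, A_max = 40,
                             omega_range = c(2 * pi / horizon, 2 * pi / 300),
                             n_starts = 8, budget = 2000, seed = 1,
                             dt = 60, rtol = 1e-6, penalty = 1e4,
                             target = "pep", final_dt = 5,
                             final_rtol = 1e-8) {
  coupling <- match.arg(coupling)
  waveform <- match.arg(waveform)
  all_members <- c(members$induced, members$repressed)
  check_cluster(net, all_members)
  m <- length(all_members)

  if (coupling == "circuit") {
    d <- 2L + m
    amp_idx <- 2L + seq_len(m)
    decode <- function(z) {
      omega <- omega_range[1] + z[1] * diff(omega_range)
      phi <- z[2] * 2 * pi
      A <- setNames(z[2 + seq_len(m)] * A_max, all_members)
      circuit_program(omega, phi, A, members, e_max = e_max,
                      waveform = waveform)
    }
    ray <- function(s, period) {
      A01 <- ifelse(all_members %in% members$induced, s * 19,
                    pmin(0.95, s * 1.9)) / A_max
      c(om01(2 * pi / period, omega_range), 0, A01)
    }
  } else {
    d <- 3L * m
    amp_idx <- seq_len(m)
    inverted <- all_members %in% members$repressed
    floors <- ifelse(all_members %in% members$induced, 1, 1 / 20)
    decode <- function(z) {
      A <- z[seq_len(m)] * A_max
      omega <- omega_range[1] + z[m + seq_len(m)] * diff(omega_range)
      phi <- z[2 * m + seq_len(m)] * 2 * pi
      forcing_program(lapply(seq_len(m), function(i) {
        enzyme_profile(all_members[i], waveform, A = A[i], omega = omega[i],
                       phi = phi[i], e_min = floors[i], e_max = e_max,
                       inverted = inverted[i])
      }))
    }
    ray <- function(s, period) {
      A01 <- ifelse(all_members %in% members$induced, s * 19,
                    pmin(0.95, s * 1.9)) / A_max
      c(A01, rep(om01(2 * pi / period, omega_range), m), rep(0, m))
    }
  }
  periods <- c(600, 1800, 3600, 14400, horizon)
  svals <- c(0.05, 0.08, 0.11, 0.14, 0.17, 0.2, 0.25, 0.35, 0.5, 0.75, 1)
  ray_starts <- unlist(lapply(periods, function(p) {
    lapply(svals, function(s) ray(s, p))
  }), recursive = FALSE)
  rnd <- lhs_starts(max(0, n_starts - 4), d, seed)
  starts <- c(list(rep(0, d)), ray_starts, rnd)
  groups <- c("base", rep(paste0("T", periods), each = length(svals)),
              rep("lhs", length(rnd)))
  backtrack <- function(z, alpha) {
    z[amp_idx] <- alpha * z[amp_idx]
    z
  }
  search <- run_search(net, decode, d, backtrack, starts, budget, seed,
                       horizon, dt, rtol, constraints, penalty, target,
                       final_dt, final_rtol, groups = groups)
  finish_optimization(net, decode, search, horizon, constraints, target,
                      seed, final_dt, final_rtol)
}

#' @export
print.pep_opt <- function(x, ...) {
  cat("<pep_opt> total", x$target, "=", format(x$objective),
      "mM.s; gain =", format(round(x$gain, 4)),
      if (x$converged) "(feasible)" else "(NOT feasible)", "\n")
  cat("  forced enzymes:", paste(names(x$program), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy/summarize optimization results
#'
#' `tidy()` returns one row per forced enzyme with the optimal waveform
#' parameters; `glance()` a one-row summary (objective in mM.s, gain ratio,
#' feasibility, evaluation count).
#'
#' @param x a `pep_opt` object.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.pep_opt <- function(x, ...) {
  if (!length(x$program)) {
    return(tibble::tibble(enzyme = character(), waveform = character(),
                          A = numeric(), omega = numeric(), phi = numeric(),
                          h = numeric(), e_min = numeric(),
                          e_max = numeric(), inverted = logical()))
  }
  dplyr::bind_rows(lapply(x$program, function(p) {
    tibble::tibble(enzyme = p$enzyme, waveform = p$waveform, A = p$A,
                   omega = p$omega, phi = p$phi, h = p$h, e_min = p$e_min,
                   e_max = p$e_max, inverted = p$inverted)
  }))
}

#' @rdname tidy.pep_opt
#' @export
glance.pep_opt <- function(x, ...) {
  tibble::tibble(objective = x$objective,
                 baseline = x$baseline_objective,
                 gain = x$gain,
                 converged = x$converged,
                 worst_violation = max(x$constraint_report$worst_violation),
                 n_eval = x$n_eval,
                 seed = x$seed)
}

#' @export
autoplot.pep_opt <- function(object, ...) {
  autoplot.ccm_trajectory(object$trajectory,
                          variables = c(object$target, names(object$program)))
}

#' Write an optimization result to JSON
#'
#' Records the optimal program, objective, gain, per-constraint worst
#' violation and seed provenance.
#'
#' @param x a `pep_opt`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_opt_json <- function(x, path) {
  jsonlite::write_json(list(
    program = program_to_list(x$program),
    objective = x$objective,
    baseline_objective = x$baseline_objective,
    gain = x$gain,
    converged = x$converged,
    constraints = x$constraint_report,
    n_eval = x$n_eval,
    seed = x$seed), path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
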
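# Forced ODE simulation and objective quantities.

# flatten network + program into the compiled model's parameter vector.
ccm_parms_vector <- function(net, program) {
  program <- validate_program(net, program)
  com <- net$cometabolites[c("atp", "adp", "amp", "nadp", "nadph", "nad",
                             "nadh")]
  kin <- unlist(net$params, use.names = FALSE)
  if (length(kin) != 120) {
    abort_config("kinetic parameter table does not match the compiled model")
  }
  forc <- matrix(0, 8, length(net$reactions))
  forc[5, ] <- 1                       # h
  forc[6, ] <- 1 / 20                  # e_min
  forc[7, ] <- 20                      # e_max
  kinds <- c(constant = 0, cosine = 1, square = 2)
  for (p in program) {
    j <- match(p$enzyme, net$reactions)
    forc[, j] <- c(kinds[[p$waveform]], p$A, p$omega, p$phi, p$h,
                   p$e_min, p$e_max, as.numeric(p$inverted))
  }
  c(net$mu, net$feed[["glcex"]], net$pts_scale, unname(com), kin,
    as.numeric(forc))
}

#' Simulate the forced network
#'
#' Integrates `dC/dt = S r(C, e(t)) + F - mu C` with a stiff-capable adaptive
#' solver (LSODA) and samples the solution on a uniform reporting grid.  The
#' shipped central carbon metabolism model runs through a compiled
#' right-hand side; other kinetics use the generic R evaluator.
#'
#' @param net a [metabolic_network()].
#' @param program a [forcing_program()] (default: unforced, all levels 1).
#' @param horizon simulation horizon, seconds (default 8 h).
#' @param init initial state, mM (default the nominal steady state).
#' @param dt reporting-grid spacing, seconds.
#' @param rtol,atol solver tolerances.
#' @param engine `"auto"`, `"compiled"` or `"r"`.
#' @return A `ccm_trajectory`: a tibble with a `time` column (s) and one
#'   column per metabolite (mM), carrying the enzyme-level matrix, the
#'   horizon and the program as attributes.
#' @export
#' @examples
#' net <- ccm_network()
#' traj <- simulate_network(net, horizon = 600, dt = 60)
#' total_metabolite(traj, "pep")
simulate_network <- function(net, program = NULL, horizon = 8 * HOUR,
                             init = net$steady_state, dt = 1,
                             rtol = 1e-8, atol = 1e-10,
                             engine = c("auto", "compiled", "r")) {
  engine <- match.arg(engine)
  if (horizon <= 0) abort_config("horizon must be positive")
  if (is.null(init)) abort_config("no initial state available")
  init <- as_state(net, init)
  if (any(init < 0)) abort_config("initial state must be non-negative")
  program <- validate_program(net, program)
  times <- seq(0, horizon, by = dt)
  if (times[length(times)] < horizon) times <- c(times, horizon)

  use_compiled <- engine == "compiled" ||
    (engine == "auto" && net$kinetics == "ecoli_ccm")
  if (use_compiled && net$kinetics != "ecoli_ccm") {
    abort_config("compiled engine only supports the shipped model")
  }
  if (use_compiled) {
    out <- deSolve::lsoda(
      y = unname(init), times = times, func = "oscimet_derivs",
      parms = ccm_parms_vector(net, program), dllname = "oscimet",
      initfunc = "oscimet_initmod", rtol = rtol, atol = atol,
      maxsteps = 50000)
  } else {
    out <- deSolve::lsoda(y = unname(init), times = times,
                          func = r_engine_rhs(net, program),
                          rtol = rtol, atol = atol, maxsteps = 50000)
  }
  if (nrow(out) < length(times) || any(!is.finite(out))) {
    last_t <- out[nrow(out), 1]
    abort_numeric(paste0("solver failed at t = ", format(last_t), " s"))
  }
  C <- out[, -1, drop = FALSE]
  if (min(C) < -1e-6) {
    abort_numeric(paste0("integration produced negative concentrations (min ",
                         format(min(C)), " mM)"))
  }
  colnames(C) <- net$metabolites
  traj <- tibble::as_tibble(cbind(data.frame(time = out[, 1]),
                                  as.data.frame(C)))
  attr(traj, "enzymes") <- program_level_matrix(net, program, out[, 1])
  attr(traj, "horizon") <- horizon
  attr(traj, "program") <- program
  attr(traj, "metabolites") <- net$metabolites
  class(traj) <- c("ccm_trajectory", class(traj))
  traj
}

# Lean right-hand-side closure for the R engine: everything the rate loop
# needs is precomputed, so per-step cost stays small.  Semantics match
# eval_profile() / the compiled model exactly.
r_engine_rhs <- function(net, program) {
  m <- length(net$reactions)
  S <- net$S
  feed <- unname(net$feed)
  mu <- net$mu
  k <- length(program)
  pidx <- match(names(program), net$reactions)
  kinds <- c(constant = 0, cosine = 1, square = 2)
  pm <- vapply(program, function(p) {
    c(kinds[[p$waveform]], p$A, p$omega, p$phi, p$h, p$e_min, p$e_max,
      as.numeric(p$inverted))
  }, numeric(8))
  base_e <- rep(1, m)
  rates_fast <- switch(net$kinetics,
    toy_chain = {
      rmax <- vapply(net$params, `[[`, numeric(1), "rmax")
      K <- vapply(net$params, `[[`, numeric(1), "K")
      sub <- net$substrate_index
      function(yc, e) e * rmax * yc[sub] / (K + yc[sub])
    },
    ecoli_ccm = {
      mets <- net$metabolites
      function(yc, e) {
        names(yc) <- mets
        e * unname(ccm_kinetic_rates(yc, net$params, net$cometabolites,
                                     net$pts_scale))
      }
    },
    abort_config(paste0("unknown kinetics family '", net$kinetics, "'")))
  function(t, y, parms) {
    yc <- pmax(y, 0)
    e <- base_e
    if (k) {
      for (j in seq_len(k)) {
        if (pm[1, j] == 0) {
          e[pidx[j]] <- pm[5, j]
        } else {
          osc <- cos(pm[3, j] * t + pm[4, j])
          if (pm[1, j] == 2) osc <- sign(osc)
          raw <- if (pm[8, j] != 0) pm[5, j] - pm[2, j] * osc else
            pm[5, j] + pm[2, j] * osc
          e[pidx[j]] <- min(max(raw, pm[6, j]), pm[7, j])
        }
      }
    }
    list(drop(S %*% rates_fast(yc, e)) + feed - mu * y)
  }
}

state_at_end <- function(traj) {
  mets <- attr(traj, "metabolites")
  unlist(traj[nrow(traj), mets])
}

#' Time-integrated metabolite amount
#'
#' Composite-trapezoid integral of one metabolite's concentration over the
#' reporting grid; the objective "total PEP" is `total_metabolite(traj,
#' "pep")` in mM.s.
#'
#' @param traj a `ccm_trajectory`.
#' @param metabolite metabolite name.
#' @return Scalar, mM.s.
#' @export
total_metabolite <- function(traj, metabolite) {
  if (!metabolite %in% attr(traj, "metabolites")) {
    abort_config(paste0("unknown metabolite '", metabolite, "'"))
  }
  t <- traj$time
  y <- traj[[metabolite]]
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Gain ratio of total metabolite between two trajectories
#'
#' @param test,baseline `ccm_trajectory` objects over equal horizons.
#' @param metabolite metabolite name (default `"pep"`).
#' @return Dimensionless ratio of time-integrated amounts.
#' @export
gain_ratio <- function(test, baseline, metabolite = "pep") {
  if (!isTRUE(all.equal(attr(test, "horizon"), attr(baseline, "horizon")))) {
    abort_config("trajectories have different horizons")
  }
  denom <- total_metabolite(baseline, metabolite)
  if (denom == 0) abort_numeric("baseline integral is zero")
  total_metabolite(test, metabolite) / denom
}

#' Tidy a trajectory into long form
#'
#' @param x a `ccm_trajectory`.
#' @param include_enzymes also stack the enzyme-level time courses.
#' @param ... unused.
#' @return Tibble with columns `time`, `variable`, `kind`, `value`.
#' @export
tidy.ccm_trajectory <- function(x, include_enzymes = FALSE, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(unclass(x)[names(x)]),
                              -"time", names_to = "variable",
                              values_to = "value")
  long$kind <- "metabolite"
  if (include_enzymes) {
    E <- attr(x, "enzymes")
    el <- tibble::tibble(
      time = rep(x$time, ncol(E)),
      variable = rep(colnames(E), each = nrow(E)),
      value = as.numeric(E),
      kind = "enzyme")
    long <- dplyr::bind_rows(long, el)
  }
  dplyr::select(long, "time", "variable", "kind", "value")
}

#' Write a trajectory to CSV
#'
#' `wide = TRUE` writes one column per variable; otherwise tidy long form.
#' A comment header records the units (time s; concentrations mM; enzyme
#' levels dimensionless).
#'
#' @param traj a `ccm_trajectory`.
#' @param path output file.
#' @param wide logical.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, wide = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# time: s; metabolite concentrations: mM; ",
                    "enzyme levels: dimensionless (e/e-hat)"), con)
  df <- if (wide) {
    cbind(tibble::as_tibble(unclass(traj)[names(traj)]),
          as.data.frame(attr(traj, "enzymes")))
  } else {
    tidy.ccm_trajectory(traj, include_enzymes = TRUE)
  }
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @export
autoplot.ccm_trajectory <- function(object, variables = NULL, ...) {
  long <- tidy.ccm_trajectory(object, include_enzymes = TRUE)
  if (!is.null(variables)) {
    long <- dplyr::filter(long, .data$variable %in% variables)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time / HOUR, y = .data$value,
                                     colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (mM) / level (-)")
}
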
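#' Metabolic network objects
#'
#' A `metabolic_network` bundles everything the ODE right-hand side needs:
#' the ordered metabolite and reaction identifiers, the stoichiometric matrix
#' `S`, per-reaction kinetic parameter vectors, fixed co-metabolite
#' concentrations, the specific growth rate `mu` (per second, equal to the
#' chemostat dilution rate), a constant feed vector (non-zero only for
#' extracellular glucose), the nominal steady-state concentration vector (mM)
#' and the list of growth-essential enzymes.
#'
#' @param metabolites,reactions character vectors of identifiers.
#' @param S stoichiometric matrix, `length(metabolites)` rows by
#'   `length(reactions)` columns, dimnames matching the identifiers.
#' @param kinetics rate-law family: `"ecoli_ccm"` (the shipped central carbon
#'   metabolism model) or `"toy_chain"`.
#' @param params named list of named numeric parameter vectors, one per
#'   reaction.
#' @param cometabolites named numeric vector of fixed co-metabolite
#'   concentrations (mM).
#' @param mu specific growth rate, 1/s.
#' @param feed named numeric vector of constant inflows (mM/s); metabolites
#'   not named receive zero.
#' @param steady_state named numeric nominal concentration vector (mM).
#' @param essential character vector of enzymes whose knockout is lethal.
#' @param pts_scale reactor-to-cytosol flux conversion applied inside the PTS
#'   rate law (dimensionless; 1 for toy networks).
#' @param extra list of additional fields (e.g. the toy substrate index).
#'
#' @return An object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions, S, kinetics, params,
                              cometabolites = numeric(), mu = 0,
                              feed = numeric(), steady_state = NULL,
                              essential = character(), pts_scale = 1,
                              extra = list()) {
  if (!all(dim(S) == c(length(metabolites), length(reactions)))) {
    abort_config("stoichiometric matrix does not match metabolite/reaction counts")
  }
  dimnames(S) <- list(metabolites, reactions)
  if (!setequal(names(params), reactions)) {
    missing <- setdiff(reactions, names(params))
    abort_config(paste0("missing kinetic parameters for reaction(s): ",
                        paste(missing, collapse = ", ")))
  }
  rmax <- vapply(params[reactions], function(p) p[["rmax"]], numeric(1))
  if (any(rmax < 0)) {
    abort_config("r_max must be non-negative for all reactions")
  }
  fv <- setNames(numeric(length(metabolites)), metabolites)
  if (length(feed)) {
    bad <- setdiff(names(feed), metabolites)
    if (length(bad)) {
      abort_config(paste0("feed names unknown metabolite(s): ",
                          paste(bad, collapse = ", ")))
    }
    fv[names(feed)] <- feed
  }
  structure(
    c(list(
      metabolites = metabolites, reactions = reactions, S = S,
      kinetics = kinetics, params = params[reactions],
      cometabolites = cometabolites, mu = mu, feed = fv,
      steady_state = steady_state, essential = essential,
      pts_scale = pts_scale), extra),
    class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", x$kinetics, ": ", length(x$metabolites),
      " metabolites, ", length(x$reactions), " reactions, mu = ",
      format(x$mu), " /s\n", sep = "")
  invisible(x)
}

#' Reaction rates with enzyme-level multipliers
#'
#' Evaluates every reaction's kinetic rate law at a concentration state and
#' multiplies it by the corresponding dimensionless enzyme level e/e-hat
#' (nominal value 1), so the rate of reaction j is linear in its own enzyme
#' level.
#'
#' @param net a [metabolic_network()].
#' @param conc named (or network-ordered) concentration vector, mM.
#' @param enzymes enzyme-level vector, one per reaction (default all 1);
#'   a named vector may set a subset, the rest staying at 1.
#' @return Named numeric vector of reaction rates, mM/s.
#' @export
rate_vector <- function(net, conc, enzymes = NULL) {
  conc <- as_state(net, conc)
  if (any(conc < -1e-9)) {
    bad <- net$metabolites[which.min(conc)]
    abort_numeric(paste0("negative concentration for metabolite '", bad,
                         "' (", format(min(conc)), " mM)"))
  }
  e <- as_levels(net, enzymes)
  r <- kinetic_rates(net, conc)
  r * e
}

kinetic_rates <- function(net, conc) {
  switch(net$kinetics,
    ecoli_ccm = ccm_kinetic_rates(conc, net$params, net$cometabolites,
                                  net$pts_scale),
    toy_chain = toy_kinetic_rates(conc, net$params, net$substrate_index),
    abort_config(paste0("unknown kinetics family '", net$kinetics, "'"))
  )
}

as_state <- function(net, conc) {
  n <- length(net$metabolites)
  if (is.null(names(conc))) {
    if (length(conc) != n) abort_config("state vector has wrong length")
    return(setNames(as.numeric(conc), net$metabolites))
  }
  bad <- setdiff(names(conc), net$metabolites)
  if (length(bad)) {
    abort_config(paste0("unknown metabolite(s): ", paste(bad, collapse = ", ")))
  }
  if (length(conc) != n) abort_config("state vector has wrong length")
  setNames(as.numeric(conc[net$metabolites]), net$metabolites)
}

as_levels <- function(net, enzymes) {
  m <- length(net$reactions)
  if (is.null(enzymes)) {
    return(setNames(rep(1, m), net$reactions))
  }
  if (is.null(names(enzymes))) {
    if (length(enzymes) != m) abort_config("enzyme-level vector has wrong length")
    e <- setNames(as.numeric(enzymes), net$reactions)
  } else {
    bad <- setdiff(names(enzymes), net$reactions)
    if (length(bad)) {
      abort_config(paste0("unknown reaction(s): ", paste(bad, collapse = ", ")))
    }
    e <- setNames(rep(1, m), net$reactions)
    e[names(enzymes)] <- as.numeric(enzymes)
  }
  if (any(e < 0)) abort_config("enzyme levels must be non-negative")
  e
}

#' ODE right-hand side: dC/dt = S r(C, e(t)) + F - mu C
#'
#' The first term is the stoichiometric sum of enzyme-scaled reaction rates,
#' `F` is the constant feed (chemostat glucose supply), and the last term is
#' the first-order dilution of every metabolite into biomass growth.
#'
#' @param net a [metabolic_network()].
#' @param t time, seconds.
#' @param conc concentration state, mM.
#' @param enzyme_fn `NULL` (all levels 1), an enzyme-level vector, or a
#'   function of time returning one (e.g. a [forcing_program()] via
#'   [program_level_fn()]).
#' @return Named derivative vector, mM/s.
#' @export
network_rhs <- function(net, t, conc, enzyme_fn = NULL) {
  if (any(!is.finite(conc))) {
    abort_numeric(paste0("non-finite state at t = ", format(t), " s"))
  }
  e <- if (is.function(enzyme_fn)) enzyme_fn(t) else enzyme_fn
  r <- rate_vector(net, conc, e)
  drop(net$S %*% r) + net$feed - net$mu * as_state(net, conc)
}

#' Steady state of the forced network at constant enzyme levels
#'
#' Relaxes the system by long-horizon integration, polishing with damped
#' Newton iterations on the right-hand side whenever the trajectory is close
#' enough, and fails loudly instead of returning a non-converged point.
#'
#' @param net a [metabolic_network()].
#' @param enzymes constant enzyme-level vector (default all 1).
#' @param guess strictly positive starting state (default the nominal steady
#'   state).
#' @param tol convergence tolerance on the max-norm of dC/dt, mM/s.
#' @param max_hours relaxation cap, simulated hours.
#' @return Named steady-state concentration vector with attribute
#'   `"residual"` (mM/s).
#' @export
find_steady_state <- function(net, enzymes = NULL, guess = net$steady_state,
                              tol = 1e-8, max_hours = 100) {
  if (is.null(guess)) abort_config("no starting guess available")
  guess <- as_state(net, guess)
  if (any(guess <= 0)) abort_config("steady-state guess must be strictly positive")
  e <- as_levels(net, enzymes)
  C <- guess
  chunk <- 10 * HOUR
  elapsed <- 0
  repeat {
    ns <- newton_steady_state(net, e, C, tol = tol)
    if (ns$ok) {
      return(structure(ns$C, residual = ns$res))
    }
    if (elapsed >= max_hours * HOUR) {
      abort_numeric(paste0(
        "steady state did not converge within ", max_hours,
        " simulated hours (final |dC/dt| = ", format(ns$res), " mM/s)"))
    }
    traj <- simulate_network(net, program = constant_program(net, e),
                             horizon = chunk, init = C, dt = chunk / 50,
                             rtol = 1e-8, atol = 1e-12)
    C <- pmax(state_at_end(traj), 1e-12)
    elapsed <- elapsed + chunk
  }
}

# Damped Newton with finite-difference Jacobian; positivity-preserving.
newton_steady_state <- function(net, e, C0, tol = 1e-8, maxit = 50) {
  C <- C0
  n <- length(C)
  f <- network_rhs(net, 0, C, e)
  for (it in seq_len(maxit)) {
    if (max(abs(f)) < tol) break
    J <- matrix(0, n, n)
    h <- pmax(abs(C), 1e-6) * 1e-7
    for (j in seq_len(n)) {
      Cp <- C
      Cp[j] <- Cp[j] + h[j]
      J[, j] <- (network_rhs(net, 0, Cp, e) - f) / h[j]
    }
    step <- tryCatch(solve(J, -f), error = function(err) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      Cn <- C + lam * step
      if (all(Cn > 0) || lam < 1e-8) break
      lam <- lam / 2
    }
    fn <- tryCatch(network_rhs(net, 0, Cn, e), error = function(err) NULL)
    if (is.null(fn) || any(!is.finite(fn))) break
    if (max(abs(fn)) > 10 * max(abs(f))) break   # diverging: hand back to relaxation
    C <- Cn
    f <- fn
  }
  res <- max(abs(f))
  list(C = C, res = res, ok = is.finite(res) && res < tol)
}

#' Nine-enzyme default path-constraint bands
#'
#' PEP is constrained to the absolute 1-10 mM window; pyruvate,
#' ribose-5-phosphate, erythrose-4-phosphate and glucose-6-phosphate to a
#' 10-fold band centred (geometrically) on their nominal steady states.
#'
#' @param net a [metabolic_network()] with a stored steady state.
#' @return Named list of `c(lo, hi)` bounds in mM.
#' @export
default_path_constraints <- function(net) {
  ss <- net$steady_state
  band <- function(m) unname(c(ss[[m]] / sqrt(10), ss[[m]] * sqrt(10)))
  cons <- list()
  if ("pep" %in% net$metabolites) cons$pep <- c(1, 10)
  for (m in intersect(c("pyr", "rib5p", "e4p", "g6p"), net$metabolites)) {
    cons[[m]] <- band(m)
  }
  cons
}
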
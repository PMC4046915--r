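#' Toy-network fixture generator
#'
#' Builds a linear irreversible Michaelis-Menten chain `M1 -> M2 -> ... ->
#' Mn -> out` fed by a constant influx into `M1`, optionally with one branch
#' drain at the middle node, and computes its strictly positive steady state
#' in closed form (each node balance is a quadratic in the concentration once
#' the incoming flux is known, so the chain solves sequentially).  The branch
#' shares its Michaelis constant with the main reaction at its node so the
#' combined drain stays a single Michaelis-Menten term.
#'
#' @param n_chain number of chain metabolites (>= 2).
#' @param branch add a branch drain at node `ceiling(n_chain / 2)`.
#' @param seed integer seed for the randomized kinetic constants.
#' @param branch_vmax optional branch capacity (mM/s); `0` gives a dead
#'   branch carrying no flux.
#' @param mu dilution rate, 1/s.
#' @return A [metabolic_network()] whose `steady_state` is the analytic
#'   solution.
#' @export
#' @examples
#' toy <- make_toy_network(3, seed = 42)
#' max(abs(network_rhs(toy, 0, toy$steady_state)))
make_toy_network <- function(n_chain, branch = FALSE, seed = 1,
                             branch_vmax = NULL, mu = 1e-4) {
  if (n_chain < 2) abort_config("n_chain must be >= 2")
  set.seed(seed)
  J <- runif(1, 0.5, 1.5)                      # influx, mM/s
  V <- runif(n_chain, 1.5 * J, 3 * J)          # capacities > influx
  K <- runif(n_chain, 0.5, 2)                  # Michaelis constants, mM
  mets <- paste0("M", seq_len(n_chain))
  rxns <- paste0("R", seq_len(n_chain))
  b <- if (branch) ceiling(n_chain / 2) else 0L
  if (branch) {
    VB <- branch_vmax %||% runif(1, 0.2 * J, 0.5 * J)
    rxns <- c(rxns, "B")
  }
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  sub <- integer(length(rxns))
  for (i in seq_len(n_chain)) {
    S[i, i] <- -1
    if (i < n_chain) S[i + 1, i] <- 1
    sub[i] <- i
  }
  params <- lapply(seq_len(n_chain), function(i) c(rmax = V[i], K = K[i]))
  names(params) <- paste0("R", seq_len(n_chain))
  if (branch) {
    S[b, "B"] <- -1
    sub[length(rxns)] <- b
    params$B <- c(rmax = VB, K = K[b])
  }

  # sequential closed-form steady state
  ss <- numeric(n_chain)
  Jin <- J
  for (i in seq_len(n_chain)) {
    Vtot <- V[i] + if (branch && i == b) params$B[["rmax"]] else 0
    bq <- Vtot + mu * K[i] - Jin
    M <- (-bq + sqrt(bq^2 + 4 * mu * Jin * K[i])) / (2 * mu)
    ss[i] <- M
    drain <- Vtot * M / (K[i] + M)
    Jin <- V[i] / Vtot * drain                  # flux continuing down the chain
  }
  names(ss) <- mets

  metabolic_network(
    metabolites = mets, reactions = rxns, S = S, kinetics = "toy_chain",
    params = params, mu = mu, feed = c(M1 = J), steady_state = ss,
    extra = list(substrate_index = sub))
}
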
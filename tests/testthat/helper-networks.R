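# Shared fixtures: the shipped central carbon metabolism network (loaded
# once) and small toy chains built in code.

ccm <- ccm_network()

toy3 <- make_toy_network(3, seed = 42)
toy_branched <- make_toy_network(4, branch = TRUE, seed = 7)

# independent numeric steady state of a toy chain: solve each node balance
# by bisection instead of the package's closed form
toy_numeric_ss <- function(net) {
  n <- length(net$metabolites)
  ss <- numeric(n)
  Jin <- net$feed[[1]]
  branch_at <- if ("B" %in% net$reactions) {
    net$substrate_index[match("B", net$reactions)]
  } else 0
  for (i in seq_len(n)) {
    p <- net$params[[paste0("R", i)]]
    Vtot <- p[["rmax"]] +
      if (i == branch_at) net$params$B[["rmax"]] else 0
    K <- p[["K"]]
    bal <- function(M) Jin - Vtot * M / (K + M) - net$mu * M
    ss[i] <- stats::uniroot(bal, c(1e-12, 1e9), tol = 1e-14)$root
    drain <- Vtot * ss[i] / (K + ss[i])
    Jin <- p[["rmax"]] / Vtot * drain
  }
  setNames(ss, net$metabolites)
}
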
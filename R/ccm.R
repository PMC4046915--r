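#' The shipped E. coli central carbon metabolism network
#'
#' Loads the calibrated 18-metabolite, 32-reaction kinetic model (glycolysis,
#' gluconeogenesis via PPS and FBP, pentose phosphate pathway) from the
#' parameter file installed with the package.  The file already contains the
#' top-down calibrated r_max values and a high-precision nominal steady
#' state, so loading is cheap and deterministic.
#'
#' @param path optional path to an alternative parameter file.
#' @return A [metabolic_network()].
#' @export
#' @examples
#' net <- ccm_network()
#' max(abs(network_rhs(net, 0, net$steady_state)))
ccm_network <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ecoli_ccm.yaml",
                                package = "oscimet", mustWork = TRUE)
  load_network(path)
}

#' Rebuild the central carbon metabolism network from its source constants
#'
#' Performs the full top-down calibration from the transcribed kinetic
#' constants and published nominal concentrations:
#' \enumerate{
#'   \item the PTS reactor-to-cytosol conversion is solved so the pyruvate
#'     balance closes at the published state;
#'   \item the glucose feed concentration is solved so the chemostat glucose
#'     balance closes;
#'   \item the gluconeogenic reactions PPS (pyruvate -> PEP) and FBP
#'     (FDP -> F6P) are assigned a nominal futile-cycle flux equal to
#'     `cycle_frac` of the glucose uptake flux, their r_max solved from their
#'     Michaelis-Menten forms, and the r_max of PK and PFK scaled up so every
#'     mass balance still closes;
#'   \item the exact steady state of the calibrated system is found by
#'     damped Newton iteration and stored as the nominal state.
#' }
#' The shipped parameter file caches the result; this routine exists so the
#' calibration is reproducible and testable.
#'
#' @param cycle_frac nominal gluconeogenic cycle flux as a fraction of the
#'   PTS uptake flux.
#' @return A calibrated [metabolic_network()].
#' @export
build_ccm_network <- function(cycle_frac = 0.01) {
  mets <- ccm_metabolites()
  params <- ccm_raw_params()
  com <- ccm_cometabolites()
  css <- ccm_published_state()
  mu <- 2.78e-5            # 0.1 / h chemostat dilution = growth rate
  cfeed <- 110.96          # feed glucose, mM

  # (1) PTS scale from pyruvate-balance closure at the published state
  raw <- ccm_kinetic_rates(css, params, com, pts_scale = 1)
  need_pts <- raw[["PDH"]] + raw[["SYN2"]] + mu * css[["pyr"]] -
    raw[["PK"]] - raw[["METSYNTH"]] - raw[["TRPSYNTH"]]
  pts_scale <- need_pts / raw[["PTS"]]

  # (2) glucose feed so the chemostat balance closes: mu (cfeed - glcex) = rPTS/scale
  cfeed <- css[["glcex"]] + raw[["PTS"]] / mu

  # (3) gluconeogenic futile cycle
  cyc <- cycle_frac * need_pts
  params$PPS[["rmax"]] <- cyc * (params$PPS[["Kpyr"]] + css[["pyr"]]) / css[["pyr"]]
  params$FBP[["rmax"]] <- cyc * (params$FBP[["Kfdp"]] + css[["fdp"]]) / css[["fdp"]]
  r2 <- ccm_kinetic_rates(css, params, com, pts_scale)
  params$PK[["rmax"]]  <- params$PK[["rmax"]] * (r2[["PK"]] + r2[["PPS"]]) / r2[["PK"]]
  params$PFK[["rmax"]] <- params$PFK[["rmax"]] * (r2[["PFK"]] + r2[["FBP"]]) / r2[["PFK"]]

  net <- metabolic_network(
    metabolites = mets, reactions = ccm_reactions(),
    S = ccm_stoichiometry(pts_scale), kinetics = "ecoli_ccm",
    params = params, cometabolites = com, mu = mu,
    feed = c(glcex = mu * cfeed), steady_state = css,
    essential = c("RPPK", "SER", "SYN1", "SYN2", "MURSYNTH", "TRPSYNTH",
                  "METSYNTH", "G3PDH", "DAHPS", "PDH"),
    pts_scale = pts_scale)

  # (4) exact nominal steady state
  ns <- newton_steady_state(net, as_levels(net, NULL), css, tol = 1e-12)
  if (!ns$ok) abort_numeric("calibration failed to converge on a steady state")
  net$steady_state <- ns$C
  net
}

#' Read and write network parameter files
#'
#' The parameter file is a single YAML document with sections `metabolites`,
#' `reactions`, `stoichiometry` (triplets), `kinetics`, `params`,
#' `cometabolites`, `mu`, `feed`, `pts_scale`, `steady_state` and
#' `essential`.  Numbers are written with 17 significant digits so a
#' load/save/load cycle is bit-exact.
#'
#' @param path file path.
#' @return `load_network()` returns a [metabolic_network()];
#'   `write_network()` returns `path` invisibly.
#' @export
load_network <- function(path) {
  if (!file.exists(path)) abort_config(paste0("no such parameter file: ", path))
  doc <- yaml::read_yaml(path)
  for (key in c("metabolites", "reactions", "stoichiometry", "kinetics",
                "params", "mu", "steady_state")) {
    if (is.null(doc[[key]])) {
      abort_config(paste0("parameter file is missing section '", key, "'"))
    }
  }
  mets <- as.character(doc$metabolites)
  rxns <- as.character(doc$reactions)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (tr in doc$stoichiometry) {
    m <- tr$metabolite
    r <- tr$reaction
    if (!(m %in% mets) || !(r %in% rxns)) {
      abort_config(paste0("stoichiometry names unknown species/reaction: ",
                          m, " / ", r))
    }
    S[m, r] <- as.numeric(tr$coef)
  }
  params <- lapply(doc$params, function(p) unlist(p))
  extra <- list()
  if (!is.null(doc$substrate_index)) {
    extra$substrate_index <- as.integer(doc$substrate_index)
  }
  metabolic_network(
    metabolites = mets, reactions = rxns, S = S,
    kinetics = doc$kinetics, params = params,
    cometabolites = unlist(doc$cometabolites) %||% numeric(),
    mu = as.numeric(doc$mu),
    feed = unlist(doc$feed) %||% numeric(),
    steady_state = unlist(doc$steady_state),
    essential = as.character(doc$essential %||% character()),
    pts_scale = as.numeric(doc$pts_scale %||% 1),
    extra = extra)
}

#' @rdname load_network
#' @param net a [metabolic_network()].
#' @export
write_network <- function(net, path) {
  num <- function(x) formatC(x, format = "g", digits = 17)
  lines <- c("# oscimet network parameter file", "")
  scalar_block <- function(name, v) {
    c(paste0(name, ":"),
      paste0("  \"", names(v), "\": ", num(unname(v))))
  }
  lines <- c(lines, "metabolites:", paste0("  - ", net$metabolites), "")
  lines <- c(lines, "reactions:", paste0("  - ", net$reactions), "")
  lines <- c(lines, "kinetics: ", "")
  lines[length(lines) - 1] <- paste0("kinetics: ", net$kinetics)
  idx <- which(net$S != 0, arr.ind = TRUE)
  lines <- c(lines, "stoichiometry:")
  for (k in seq_len(nrow(idx))) {
    lines <- c(lines, paste0(
      "  - {metabolite: ", net$metabolites[idx[k, 1]],
      ", reaction: ", net$reactions[idx[k, 2]],
      ", coef: ", num(net$S[idx[k, 1], idx[k, 2]]), "}"))
  }
  lines <- c(lines, "", "params:")
  for (rx in net$reactions) {
    p <- net$params[[rx]]
    lines <- c(lines, paste0("  ", rx, ":"),
               paste0("    \"", names(p), "\": ", num(unname(p))))
  }
  lines <- c(lines, "")
  if (length(net$cometabolites)) {
    lines <- c(lines, scalar_block("cometabolites", net$cometabolites), "")
  }
  lines <- c(lines, paste0("mu: ", num(net$mu)))
  lines <- c(lines, paste0("pts_scale: ", num(net$pts_scale)))
  fnz <- net$feed[net$feed != 0]
  if (length(fnz)) lines <- c(lines, scalar_block("feed", fnz))
  lines <- c(lines, scalar_block("steady_state", net$steady_state))
  if (length(net$essential)) {
    lines <- c(lines, "essential:", paste0("  - ", net$essential))
  }
  if (!is.null(net$substrate_index)) {
    lines <- c(lines, paste0("substrate_index: [",
                             paste(net$substrate_index, collapse = ", "), "]"))
  }
  writeLines(lines, path)
  invisible(path)
}
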
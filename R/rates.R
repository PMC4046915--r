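# Rate laws of the extended E. coli central carbon metabolism model.
#
# Conventions: intracellular concentrations in mM (per litre cytosol), time in
# seconds, rates in mM/s.  Extracellular glucose (state "glcex") is carried in
# mM per litre of reactor volume; the PTS rate law below is multiplied by
# `pts_scale` (biomass density over cell specific weight, ~65) so that the
# value entering the intracellular balances is on the cytosolic scale, and the
# glucose balance consumes rate/pts_scale.

ccm_metabolites <- function() {
  c("glcex", "g6p", "f6p", "fdp", "gap", "dhap", "pgp", "pg3", "pg2", "pep",
    "pyr", "pg6", "ribu5p", "xyl5p", "sed7p", "rib5p", "e4p", "g1p")
}

ccm_reactions <- function() {
  c("PTS", "PGI", "PGM", "G6PDH", "PFK", "TA", "TKA", "TKB", "MURSYNTH",
    "ALDO", "GAPDH", "TIS", "TRPSYNTH", "G3PDH", "PGK", "SER", "PGLUMU",
    "ENO", "PK", "PEPC", "SYN1", "SYN2", "DAHPS", "PDH", "METSYNTH", "PGDH",
    "R5PI", "RU5P", "RPPK", "G1PAT", "PPS", "FBP")
}

# Kinetic constants of the 30 source-model reactions (glycolysis + pentose
# phosphate pathway, co-metabolites fixed) plus Michaelis-Menten forms for the
# two gluconeogenic reactions PPS and FBP, whose r_max values start at 0 and
# are assigned by the top-down calibration (see calibrate_gluconeogenesis).
ccm_raw_params <- function() {
  list(
    PTS      = c(rmax = 7829.78, Ka1 = 3082.3, Ka2 = 0.01, Ka3 = 245.3,
                 Kg6p = 2.15, n = 3.66),
    PGI      = c(rmax = 650.988, Keq = 0.1725, Kg6p = 2.9, Kf6p = 0.266,
                 Kf6p_6pginh = 0.2, Kg6p_6pginh = 0.2),
    PGM      = c(rmax = 0.839824, Keq = 0.196, Kg6p = 1.038, Kg1p = 0.0136),
    G6PDH    = c(rmax = 1.3802, Kg6p = 14.4, Knadp = 0.0246,
                 Knadph_g6pinh = 6.43, Knadph_nadpinh = 0.01),
    PFK      = c(rmax = 1840.58, Katp_s = 0.123, Kadp_c = 4.14,
                 Kf6p_s = 0.325, Kpep = 3.26, Kadp_b = 3.89, Kamp_b = 3.2,
                 Kadp_a = 128, Kamp_a = 19.1, L = 5629067, n = 11.1),
    TA       = c(rmax = 10.8716, Keq = 1.05),
    TKA      = c(rmax = 9.47338, Keq = 1.2),
    TKB      = c(rmax = 86.5586, Keq = 10),
    MURSYNTH = c(rmax = 0.00043711),
    ALDO     = c(rmax = 17.4146, Keq = 0.144, Kfdp = 1.75, Kgap = 0.088,
                 Kdhap = 0.088, Kgapinh = 0.6, blf = 2),
    GAPDH    = c(rmax = 921.594, Keq = 0.63, Kgap = 0.683, Kpgp = 1.04e-05,
                 Knad = 0.252, Knadh = 1.09),
    TIS      = c(rmax = 68.6747, Keq = 1.39, Kdhap = 2.8, Kgap = 0.3),
    TRPSYNTH = c(rmax = 0.001037),
    G3PDH    = c(rmax = 0.0116204, Kdhap = 1),
    PGK      = c(rmax = 3021.77, Keq = 1934.4, Kadp = 0.185, Katp = 0.653,
                 Kpgp = 0.0468, Kpg3 = 0.473),
    SER      = c(rmax = 0.025712, Kpg3 = 1),
    PGLUMU   = c(rmax = 89.0497, Keq = 0.188, Kpg3 = 0.2, Kpg2 = 0.369),
    ENO      = c(rmax = 330.448, Keq = 6.73, Kpg2 = 0.1, Kpep = 0.135),
    PK       = c(rmax = 0.0611315, Kpep = 0.31, Kadp = 0.26, Katp = 22.5,
                 Kfdp = 0.19, Kamp = 0.2, L = 1000, n = 4),
    PEPC     = c(rmax = 0.107021, Kpep = 4.07, Kfdp = 0.7, n = 4.21),
    SYN1     = c(rmax = 0.019539, Kpep = 1),
    SYN2     = c(rmax = 0.0736186, Kpyr = 1),
    DAHPS    = c(rmax = 0.107953, Ke4p = 0.035, Kpep = 0.0053, ne4p = 2.6,
                 npep = 2.2),
    PDH      = c(rmax = 6.05953, Kpyr = 1159, n = 3.68),
    METSYNTH = c(rmax = 0.0022627),
    PGDH     = c(rmax = 16.2324, Kpg6 = 37.5, Knadp = 0.0506,
                 Knadphinh = 0.0138, Katpinh = 208),
    R5PI     = c(rmax = 4.83841, Keq = 4),
    RU5P     = c(rmax = 6.73903, Keq = 1.4),
    RPPK     = c(rmax = 0.0129005, Krib5p = 0.1),
    G1PAT    = c(rmax = 0.00752546, Kg1p = 3.2, Katp = 4.42, Kfdp = 0.119,
                 n = 1.2),
    PPS      = c(rmax = 0, Kpyr = 0.083),
    FBP      = c(rmax = 0, Kfdp = 0.015)
  )
}

# Published nominal concentrations of the source model (mM); used as the
# starting guess for the high-precision steady state stored in the shipped
# parameter file.
ccm_published_state <- function() {
  c(glcex = 0.0556, g6p = 3.48, f6p = 0.6, fdp = 0.272, gap = 0.218,
    dhap = 0.167, pgp = 0.008, pg3 = 2.13, pg2 = 0.399, pep = 2.67,
    pyr = 2.67, pg6 = 0.808, ribu5p = 0.111, xyl5p = 0.138, sed7p = 0.276,
    rib5p = 0.398, e4p = 0.098, g1p = 0.653)
}

ccm_cometabolites <- function() {
  c(atp = 4.27, adp = 0.595, amp = 0.955, nadp = 0.195, nadph = 0.062,
    nad = 1.47, nadh = 0.1)
}

ccm_stoichiometry <- function(pts_scale) {
  mets <- ccm_metabolites()
  rxns <- ccm_reactions()
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  add <- function(rx, ...) {
    v <- c(...)
    S[names(v), rx] <<- v
  }
  add("PTS", glcex = -1 / pts_scale, g6p = 1, pep = -1, pyr = 1)
  add("PGI", g6p = -1, f6p = 1)
  add("PGM", g6p = -1, g1p = 1)
  add("G6PDH", g6p = -1, pg6 = 1)
  add("PFK", f6p = -1, fdp = 1)
  add("TA", gap = -1, sed7p = -1, e4p = 1, f6p = 1)
  add("TKA", rib5p = -1, xyl5p = -1, sed7p = 1, gap = 1)
  add("TKB", xyl5p = -1, e4p = -1, f6p = 1, gap = 1)
  add("MURSYNTH", f6p = -2)
  add("ALDO", fdp = -1, gap = 1, dhap = 1)
  add("GAPDH", gap = -1, pgp = 1)
  add("TIS", dhap = -1, gap = 1)
  add("TRPSYNTH", gap = 1, pyr = 1)
  add("G3PDH", dhap = -1)
  add("PGK", pgp = -1, pg3 = 1)
  add("SER", pg3 = -1)
  add("PGLUMU", pg3 = -1, pg2 = 1)
  add("ENO", pg2 = -1, pep = 1)
  add("PK", pep = -1, pyr = 1)
  add("PEPC", pep = -1)
  add("SYN1", pep = -1)
  add("SYN2", pyr = -1)
  add("DAHPS", pep = -1, e4p = -1)
  add("PDH", pyr = -1)
  add("METSYNTH", pyr = 1)
  add("PGDH", pg6 = -1, ribu5p = 1)
  add("R5PI", ribu5p = -1, rib5p = 1)
  add("RU5P", ribu5p = -1, xyl5p = 1)
  add("RPPK", rib5p = -1)
  add("G1PAT", g1p = -1)
  add("PPS", pyr = -1, pep = 1)
  add("FBP", fdp = -1, f6p = 1)
  S
}

# Kinetic rates (before the enzyme-level multiplier) at one state, mM/s.
# `conc` may contain small negative solver noise; it is clipped at zero.
ccm_kinetic_rates <- function(conc, params, cometabolites, pts_scale) {
  C <- pmax(conc, 0)
  env <- c(as.list(C), as.list(cometabolites))
  with(env, {
    r <- numeric(32)
    names(r) <- ccm_reactions()
    p <- params$PTS
    pr <- pep / pyr
    r["PTS"] <- pts_scale * p[["rmax"]] * glcex * pr /
      ((p[["Ka1"]] + p[["Ka2"]] * pr + p[["Ka3"]] * glcex + glcex * pr) *
         (1 + g6p^p[["n"]] / p[["Kg6p"]]))
    p <- params$PGI
    r["PGI"] <- p[["rmax"]] * (g6p - f6p / p[["Keq"]]) /
      (p[["Kg6p"]] * (1 + f6p / (p[["Kf6p"]] * (1 + pg6 / p[["Kf6p_6pginh"]])) +
                        pg6 / p[["Kg6p_6pginh"]]) + g6p)
    p <- params$PGM
    r["PGM"] <- p[["rmax"]] * (g6p - g1p / p[["Keq"]]) /
      (p[["Kg6p"]] * (1 + g1p / p[["Kg1p"]]) + g6p)
    p <- params$G6PDH
    r["G6PDH"] <- p[["rmax"]] * g6p * nadp /
      ((g6p + p[["Kg6p"]]) * (1 + nadph / p[["Knadph_g6pinh"]]) *
         (p[["Knadp"]] * (1 + nadph / p[["Knadph_nadpinh"]]) + nadp))
    p <- params$PFK
    a1 <- 1 + adp / p[["Kadp_a"]] + amp / p[["Kamp_a"]]
    b1 <- 1 + pep / p[["Kpep"]] + adp / p[["Kadp_b"]] + amp / p[["Kamp_b"]]
    r["PFK"] <- p[["rmax"]] * atp * f6p /
      ((atp + p[["Katp_s"]] * (1 + adp / p[["Kadp_c"]])) *
         (f6p + p[["Kf6p_s"]] * b1 / a1) *
         (1 + p[["L"]] / (1 + f6p * a1 / (p[["Kf6p_s"]] * b1))^p[["n"]]))
    p <- params$TA
    r["TA"] <- p[["rmax"]] * (gap * sed7p - e4p * f6p / p[["Keq"]])
    p <- params$TKA
    r["TKA"] <- p[["rmax"]] * (rib5p * xyl5p - sed7p * gap / p[["Keq"]])
    p <- params$TKB
    r["TKB"] <- p[["rmax"]] * (xyl5p * e4p - f6p * gap / p[["Keq"]])
    r["MURSYNTH"] <- params$MURSYNTH[["rmax"]]
    p <- params$ALDO
    r["ALDO"] <- p[["rmax"]] * (fdp - gap * dhap / p[["Keq"]]) /
      (p[["Kfdp"]] + fdp + p[["Kgap"]] * dhap / (p[["Keq"]] * p[["blf"]]) +
         p[["Kdhap"]] * gap / (p[["Keq"]] * p[["blf"]]) +
         fdp * gap / p[["Kgapinh"]] +
         gap * dhap / (p[["Keq"]] * p[["blf"]]))
    p <- params$GAPDH
    r["GAPDH"] <- p[["rmax"]] * (gap * nad - pgp * nadh / p[["Keq"]]) /
      ((p[["Kgap"]] * (1 + pgp / p[["Kpgp"]]) + gap) *
         (p[["Knad"]] * (1 + nadh / p[["Knadh"]]) + nad))
    p <- params$TIS
    r["TIS"] <- p[["rmax"]] * (dhap - gap / p[["Keq"]]) /
      (p[["Kdhap"]] * (1 + gap / p[["Kgap"]]) + dhap)
    r["TRPSYNTH"] <- params$TRPSYNTH[["rmax"]]
    p <- params$G3PDH
    r["G3PDH"] <- p[["rmax"]] * dhap / (p[["Kdhap"]] + dhap)
    p <- params$PGK
    r["PGK"] <- p[["rmax"]] * (adp * pgp - atp * pg3 / p[["Keq"]]) /
      ((p[["Kadp"]] * (1 + atp / p[["Katp"]]) + adp) *
         (p[["Kpgp"]] * (1 + pg3 / p[["Kpg3"]]) + pgp))
    p <- params$SER
    r["SER"] <- p[["rmax"]] * pg3 / (p[["Kpg3"]] + pg3)
    p <- params$PGLUMU
    r["PGLUMU"] <- p[["rmax"]] * (pg3 - pg2 / p[["Keq"]]) /
      (p[["Kpg3"]] * (1 + pg2 / p[["Kpg2"]]) + pg3)
    p <- params$ENO
    r["ENO"] <- p[["rmax"]] * (pg2 - pep / p[["Keq"]]) /
      (p[["Kpg2"]] * (1 + pep / p[["Kpep"]]) + pg2)
    p <- params$PK
    x <- pep / p[["Kpep"]] + 1
    r["PK"] <- p[["rmax"]] * pep * x^(p[["n"]] - 1) * adp /
      (p[["Kpep"]] *
         (p[["L"]] * ((1 + atp / p[["Katp"]]) /
                        (fdp / p[["Kfdp"]] + amp / p[["Kamp"]] + 1))^p[["n"]] +
            x^p[["n"]]) *
         (adp + p[["Kadp"]]))
    p <- params$PEPC
    r["PEPC"] <- p[["rmax"]] * pep * (1 + (fdp / p[["Kfdp"]])^p[["n"]]) /
      (p[["Kpep"]] + pep)
    p <- params$SYN1
    r["SYN1"] <- p[["rmax"]] * pep / (p[["Kpep"]] + pep)
    p <- params$SYN2
    r["SYN2"] <- p[["rmax"]] * pyr / (p[["Kpyr"]] + pyr)
    p <- params$DAHPS
    r["DAHPS"] <- p[["rmax"]] * e4p^p[["ne4p"]] * pep^p[["npep"]] /
      ((p[["Ke4p"]] + e4p^p[["ne4p"]]) * (p[["Kpep"]] + pep^p[["npep"]]))
    p <- params$PDH
    r["PDH"] <- p[["rmax"]] * pyr^p[["n"]] / (p[["Kpyr"]] + pyr^p[["n"]])
    r["METSYNTH"] <- params$METSYNTH[["rmax"]]
    p <- params$PGDH
    r["PGDH"] <- p[["rmax"]] * pg6 * nadp /
      ((pg6 + p[["Kpg6"]]) *
         (nadp + p[["Knadp"]] * (1 + nadph / p[["Knadphinh"]]) *
            (1 + atp / p[["Katpinh"]])))
    p <- params$R5PI
    r["R5PI"] <- p[["rmax"]] * (ribu5p - rib5p / p[["Keq"]])
    p <- params$RU5P
    r["RU5P"] <- p[["rmax"]] * (ribu5p - xyl5p / p[["Keq"]])
    p <- params$RPPK
    r["RPPK"] <- p[["rmax"]] * rib5p / (p[["Krib5p"]] + rib5p)
    p <- params$G1PAT
    r["G1PAT"] <- p[["rmax"]] * g1p * atp * (1 + (fdp / p[["Kfdp"]])^p[["n"]]) /
      ((p[["Katp"]] + atp) * (p[["Kg1p"]] + g1p))
    p <- params$PPS
    r["PPS"] <- p[["rmax"]] * pyr / (p[["Kpyr"]] + pyr)
    p <- params$FBP
    r["FBP"] <- p[["rmax"]] * fdp / (p[["Kfdp"]] + fdp)
    r
  })
}

# Toy-chain kinetics: irreversible Michaelis-Menten steps, parameters
# c(rmax, K) per reaction and a `substrate` index per reaction.
toy_kinetic_rates <- function(conc, params, substrate_index) {
  C <- pmax(conc, 0)
  v <- vapply(seq_along(params), function(j) {
    p <- params[[j]]
    s <- C[substrate_index[j]]
    p[["rmax"]] * s / (p[["K"]] + s)
  }, numeric(1))
  names(v) <- names(params)
  v
}
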
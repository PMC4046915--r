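#' Export the network structure as SBML Level 3
#'
#' Writes an SBML Level 3 Version 2 document with the compartment, all
#' species (co-metabolites as boundary species), all reactions with their
#' stoichiometry, and every kinetic constant as a reaction-local parameter.
#' The rate-law mathematics itself is not serialized to MathML; the document
#' is a structural interchange format, and the kinetics live in this
#' package's parameter file.
#'
#' @param net a [metabolic_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(net, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "central_carbon_metabolism",
                               substanceUnits = "millimole",
                               timeUnits = "second")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cytosol", constant = "true",
                      spatialDimensions = "3", size = "1")
  species <- xml2::xml_add_child(model, "listOfSpecies")
  for (m in net$metabolites) {
    xml2::xml_add_child(species, "species", id = m, compartment = "cytosol",
                        initialConcentration =
                          format(net$steady_state[[m]], digits = 17),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  for (m in names(net$cometabolites)) {
    xml2::xml_add_child(species, "species", id = m, compartment = "cytosol",
                        initialConcentration =
                          format(net$cometabolites[[m]], digits = 17),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "true", constant = "true")
  }
  reactions <- xml2::xml_add_child(model, "listOfReactions")
  for (rx in net$reactions) {
    rnode <- xml2::xml_add_child(reactions, "reaction", id = rx,
                                 reversible = "true")
    coef <- net$S[, rx]
    sub <- names(coef)[coef < 0]
    prod <- names(coef)[coef > 0]
    if (length(sub)) {
      ls <- xml2::xml_add_child(rnode, "listOfReactants")
      for (m in sub) {
        xml2::xml_add_child(ls, "speciesReference", species = m,
                            stoichiometry = format(abs(coef[[m]]),
                                                   digits = 17),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rnode, "listOfProducts")
      for (m in prod) {
        xml2::xml_add_child(lp, "speciesReference", species = m,
                            stoichiometry = format(coef[[m]], digits = 17),
                            constant = "true")
      }
    }
    kl <- xml2::xml_add_child(rnode, "kineticLaw")
    lop <- xml2::xml_add_child(kl, "listOfLocalParameters")
    p <- net$params[[rx]]
    for (nm in names(p)) {
      xml2::xml_add_child(lop, "localParameter", id = nm,
                          value = format(p[[nm]], digits = 17))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
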
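#' Read a reaction network from an SBML file
#'
#' Parses SBML Level 2 or Level 3 and keeps only the structural part of the
#' model: species, and the reactants and products of each reaction.
#' Modifiers, rules, events, kinetic laws, units and the `constant` /
#' `boundaryCondition` flags of species are ignored; such species are
#' treated as ordinary species. Reversible reactions are expanded into two
#' separate irreversible reactions (ids `<id>` and `<id>_rev`), so the
#' resulting network contains one column per reaction direction.
#'
#' Stoichiometries must be integral: values are rounded to the nearest
#' integer and an error is raised when a value deviates from an integer by
#' more than `1e-9`.
#'
#' @param path path to an SBML file
#' @return a `reaction_network`; species order follows `listOfSpecies`,
#'   with species only referenced by reactions appended
#' @export
#' @examples
#' f <- system.file("extdata", "mirna.xml", package = "dosor")
#' net <- read_sbml(f)
#' c(n_species(net), n_reactions(net))
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("not a readable SBML/XML file: ", path, " (", conditionMessage(e), ")")
  })
  xml2::xml_ns_strip(doc)
  if (!identical(xml2::xml_name(doc), "sbml")) {
    stop("file has no <sbml> root element: ", path)
  }
  level <- xml2::xml_attr(doc, "level")
  sp_nodes <- xml2::xml_find_all(doc, ".//model/listOfSpecies/species")
  species <- xml2::xml_attr(sp_nodes, "id")
  sp_names <- xml2::xml_attr(sp_nodes, "name")
  keep <- !is.na(sp_names)
  species_names <- if (any(keep)) stats::setNames(sp_names[keep], species[keep]) else NULL

  reactions <- list()
  for (rnode in xml2::xml_find_all(doc, ".//model/listOfReactions/reaction")) {
    rid <- xml2::xml_attr(rnode, "id")
    if (is.na(rid)) stop("reaction without id in ", path)
    reactants <- .sbml_side(rnode, "listOfReactants", rid, level)
    products <- .sbml_side(rnode, "listOfProducts", rid, level)
    ## SBML L2 reactions are reversible unless stated otherwise; L3 requires
    ## the attribute.  A reversible reaction becomes a forward/reverse pair.
    rev <- xml2::xml_attr(rnode, "reversible")
    rev <- if (is.na(rev)) TRUE else identical(rev, "true")
    reactions[[length(reactions) + 1]] <-
      list(id = rid, reactants = reactants, products = products)
    if (rev) {
      reactions[[length(reactions) + 1]] <-
        list(id = paste0(rid, "_rev"), reactants = products, products = reactants)
    }
  }
  all_species <- unique(c(species, unlist(lapply(reactions, function(r) {
    c(names(r$reactants), names(r$products))
  }), use.names = FALSE)))
  reaction_network(reactions, species = all_species, species_names = species_names)
}

## collect one side of an SBML reaction as a named coefficient vector
.sbml_side <- function(rnode, listname, rid, level) {
  refs <- xml2::xml_find_all(rnode, paste0("./", listname, "/speciesReference"))
  if (!length(refs)) return(NULL)
  sp <- xml2::xml_attr(refs, "species")
  st <- xml2::xml_attr(refs, "stoichiometry")
  st <- ifelse(is.na(st), 1, suppressWarnings(as.numeric(st)))
  if (anyNA(st)) stop("reaction ", rid, ": non-numeric stoichiometry")
  bad <- abs(st - round(st)) > 1e-9
  if (any(bad)) {
    stop("reaction ", rid, ": non-integer stoichiometry for species ",
         paste(sp[bad], collapse = ", "))
  }
  out <- tapply(round(st), sp, sum)  # merge duplicate speciesReferences
  stats::setNames(as.numeric(out), names(out))
}
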
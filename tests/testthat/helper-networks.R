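## shared helpers for the test suite

## canonical string keys for collections of sets, order-independent
set_keys <- function(sets) {
  sort(vapply(sets, function(x) paste(sort(x), collapse = "+"), ""))
}

sor_keys <- function(sor_set) set_keys(lapply(sor_set$sors, `[[`, "reactions"))
do_keys <- function(do_set) set_keys(lapply(do_set$dos, `[[`, "species"))

expect_same_sets <- function(a, b) expect_identical(set_keys(a), set_keys(b))

## two-species toy: A catalyses B, B drains
toy_net <- function() {
  read_reaction_text(c("p: A -> A + B", "d: B -> 0"))
}

## minimal SBML document with a single (optionally reversible) reaction
sbml_doc <- function(reversible = "false", stoich_b = "1") {
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
    '<model id="m"><listOfSpecies>',
    '<species id="A"/><species id="B"/>',
    '</listOfSpecies><listOfReactions>',
    sprintf('<reaction id="r" reversible="%s">', reversible),
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>',
    sprintf('<listOfProducts><speciesReference species="B" stoichiometry="%s"/></listOfProducts>',
            stoich_b),
    '</reaction></listOfReactions></model></sbml>')
}

write_sbml_fixture <- function(lines) {
  f <- tempfile(fileext = ".xml")
  writeLines(lines, f)
  f
}

## the 8 SORs of the micro-RNA model, derived by hand from the reaction
## list (closure + Nv >= 0 checks per ERC-closed candidate set)
mirna_sor_sets <- function() {
  list(
    character(0),
    c("r3", "r4", "r5", "r6"),
    c("r7", "r8", "r10", "r11"),
    c("r1", "r2", "r7", "r8", "r10", "r11"),
    c("r3", "r4", "r5", "r6", "r7", "r8", "r10", "r11"),
    c("r3", "r4", "r5", "r6", "r7", "r8", "r9", "r10", "r11"),
    c("r1", "r2", "r3", "r4", "r5", "r6", "r7", "r8", "r10", "r11"),
    paste0("r", 1:11)
  )
}
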
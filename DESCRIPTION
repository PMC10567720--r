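Package: dosor
Title: Distributed Organizations and Organizational Reaction Sets of Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Structural analysis of reaction networks in the sense of chemical
    organization theory. Computes species closures, elementary reaction
    closures (ERCs), and enumerates all sets of organizational reactions
    (SORs) and all distributed organizations (DOs) of a network by
    mixed-integer linear programming with integer cuts, using a built-in
    exact branch-and-bound solver over a dense two-phase simplex. For every
    DO-SOR pair it derives the maximal compartments and a minimal
    compartmentalization (a set-cover integer program), classifies
    organizations versus genuine distributed organizations, and builds the
    annotated lattices of SORs and DOs with Graphviz DOT export. Reaction
    networks are read from SBML Level 2/3 files (reactants and products
    only) or from a plain-text reaction notation; a seeded random-network
    generator and definition-level brute-force oracles support property
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
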
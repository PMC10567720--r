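test_that("plain-text notation parses, round-trips and validates", {
  net <- read_reaction_text(c(
    "# comment",
    "r6: miR -> Sink",
    "r7: Signal -> Signal + TF1_mRNA",
    "rx: -> A",
    "ry: 2 B + C -> 0"
  ))
  expect_equal(n_reactions(net), 4)
  expect_equal(reaction_support(net, "r6"), "miR")
  expect_equal(reaction_products(net, "r6"), "Sink")
  ## catalytic: Signal on both sides
  expect_true("Signal" %in% reaction_support(net, "r7"))
  expect_true("Signal" %in% reaction_products(net, "r7"))
  expect_equal(inflow_reactions(net), "rx")
  expect_length(reaction_support(net, "rx"), 0)
  expect_equal(net$reactions$ry$reactants[["B"]], 2)
  ## species collected in first-occurrence order
  expect_equal(net$species[1:2], c("miR", "Sink"))
  ## round trip
  rt <- read_reaction_text(write_reaction_text(net))
  expect_identical(rt$species, net$species)
  expect_identical(rt$reactions, net$reactions)
  ## errors carry line positions
  expect_error(read_reaction_text("r1: A -> B -> C"), "one '->'")
  expect_error(read_reaction_text("r1: A + A -> B"), "repeated")
})

test_that("stoichiometric matrix is products minus reactants, catalysts zero", {
  net <- example_network("mirna")
  N <- stoichiometric_matrix(net)
  expect_equal(dim(N), c(9, 11))
  ## r7 (Signal -> Signal + TF1_mRNA): +1 TF1_mRNA, 0 Signal
  expect_equal(N["TF1_mRNA", "r7"], 1)
  expect_equal(N["Signal", "r7"], 0)
  ## r9 consumes TF1_mRNA, keeps miR
  expect_equal(N["TF1_mRNA", "r9"], -1)
  expect_equal(N["miR", "r9"], 0)
  net3 <- example_network("three_generator")
  N3 <- stoichiometric_matrix(net3)
  ## R6: B1 + B3 -> 2 B2
  expect_equal(N3[c("B1", "B3", "B2"), "R6"], c(B1 = -1, B3 = -1, B2 = 2))
  ## columns reproduce product minus reactant vectors for every reaction
  for (rid in reaction_ids(net3)) {
    r <- net3$reactions[[rid]]
    expected <- stats::setNames(numeric(n_species(net3)), net3$species)
    expected[names(r$products)] <- expected[names(r$products)] + r$products
    expected[names(r$reactants)] <- expected[names(r$reactants)] - r$reactants
    expect_equal(N3[, rid], expected)
  }
  ## empty network
  expect_equal(dim(stoichiometric_matrix(reaction_network())), c(0, 0))
})

test_that("SBML reading keeps structure only and expands reversible reactions", {
  f <- system.file("extdata", "mirna.xml", package = "dosor")
  net <- read_sbml(f)
  expect_equal(n_species(net), 9)
  expect_equal(n_reactions(net), 11)
  ## same reaction structure as the text fixture
  expect_identical(stoichiometric_matrix(net)[net$species, ],
                   stoichiometric_matrix(example_network("mirna"))[net$species, ])
  ## reversible A <-> B becomes two mutually inverse columns
  rev <- read_sbml(write_sbml_fixture(sbml_doc(reversible = "true")))
  expect_equal(n_reactions(rev), 2)
  N <- stoichiometric_matrix(rev)
  expect_equal(N[, 1], -N[, 2])
  ## non-integer stoichiometry is rejected with the species named
  expect_error(read_sbml(write_sbml_fixture(sbml_doc(stoich_b = "1.5"))),
               "non-integer stoichiometry.*B")
  ## no reactions is a valid model
  empty <- read_sbml(write_sbml_fixture(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m"><listOfSpecies><species id="A"/></listOfSpecies></model></sbml>')))
  expect_equal(n_reactions(empty), 0)
  expect_equal(n_species(empty), 1)
  expect_error(read_sbml(write_sbml_fixture("not xml")), "not a readable")
})

test_that("fixtures match their printed sizes and species", {
  net <- example_network("mirna")
  expect_equal(n_species(net), 9)
  expect_equal(n_reactions(net), 11)
  net3 <- example_network("three_generator")
  expect_equal(n_reactions(net3), 9)
  expect_setequal(net3$species, c("A1", "A2", "A3", "B1", "B2", "B3", "D1"))
  expect_error(example_network("nope"))
})

test_that("duplicate reactions stay distinct columns; constructor validates", {
  net <- reaction_network(list(
    list(id = "a", reactants = c(X = 1), products = c(Y = 1)),
    list(id = "b", reactants = c(X = 1), products = c(Y = 1))
  ))
  expect_equal(n_reactions(net), 2)
  ercs <- create_ercs(net)
  expect_setequal(ercs$a$reactions, ercs$b$reactions)
  expect_error(reaction_network(list(
    list(id = "a", reactants = c(X = 1), products = NULL),
    list(id = "a", reactants = c(Y = 1), products = NULL)
  )), "duplicate reaction ids")
  expect_error(reaction_network(list(
    list(id = "a", reactants = c(X = 0.5), products = NULL)
  )), "non-integer")
  expect_error(
    reaction_network(list(list(id = "a", reactants = c(X = 1), products = NULL)),
                     species = "Y"),
    "unknown species"
  )
})
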
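test_that("species_of_sor is the union of supports and products", {
  net <- example_network("mirna")
  expect_length(species_of_sor(net, character(0)), 0)
  expect_setequal(species_of_sor(net, "r6"), c("miR", "Sink"))
  net3 <- example_network("three_generator")
  expect_setequal(species_of_sor(net3, c("R1", "R2", "R3")),
                  c("A1", "A2", "A3", "B1", "B2", "B3"))
})

test_that("maximal compartments of the worked micro-RNA SOR are reproduced", {
  net <- example_network("mirna")
  sor <- c("r3", "r4", "r5", "r6", "r7", "r8", "r10", "r11")
  mcs <- create_mcs(net, sor, net$species)
  expect_length(mcs, 3)
  expect_same_sets(mcs, list(
    c("Signal", "Sink", "TF2", "TF1_mRNA", "TF1"),
    c("Sink", "miR_gene", "TF2", "miR_gene_TF2", "miR"),
    c("Sink", "TF2", "miR", "TF1")
  ))
  ## each MC: closed, supports only SOR reactions, and is maximal
  for (mc in mcs) {
    expect_setequal(species_closure(net, mc), mc)
    expect_true(all(supported_reactions(net, mc) %in% sor))
    for (extra in setdiff(net$species, mc)) {
      grown <- c(mc, extra)
      broken <- !all(supported_reactions(net, grown) %in% sor) ||
        !setequal(species_closure(net, grown), grown)
      expect_true(broken, label = paste("adding", extra, "must break the MC"))
    }
  }
  ## and the minimal compartmentalization needs exactly 2 of them
  cov <- get_min_compartments(net, sor, mcs)
  expect_length(cov, 2)
  ## the cover satisfies both constraint families verbatim
  expect_true(all(species_of_sor(net, sor) %in% unique(unlist(cov))))
  for (r in sor) {
    expect_true(any(vapply(cov, function(mc) {
      all(reaction_support(net, r) %in% mc)
    }, TRUE)))
  }
  ## cover size is invariant under permutation of the MC list
  for (i in 1:3) {
    expect_length(get_min_compartments(net, sor, sample(mcs)), 2)
  }
})

test_that("a closed DO supporting exactly the SOR is its own single MC", {
  net <- example_network("mirna")
  do <- c("miR_gene", "TF2", "miR_gene_TF2", "miR", "Sink")
  sor <- c("r3", "r4", "r5", "r6")
  mcs <- create_mcs(net, sor, do)
  expect_length(mcs, 1)
  expect_setequal(mcs[[1]], do)
  expect_length(get_min_compartments(net, sor, mcs), 1)
  expect_error(create_mcs(net, sor, "miR"), "must contain")
})

test_that("create_mcs equals the exhaustive subset oracle", {
  net <- example_network("mirna")
  sor <- c("r3", "r4", "r5", "r6", "r7", "r8", "r10", "r11")
  expect_same_sets(create_mcs(net, sor, net$species),
                   oracle_mcs(net, sor, net$species))
  for (seed in 1:15) {
    rn <- random_network(6, 7, seed = 600 + seed)
    for (s in all_sors(rn, annotate = FALSE)$sors) {
      dmin <- min_do_of_sor(rn, s$reactions)
      expect_same_sets(create_mcs(rn, s$reactions, dmin),
                       oracle_mcs(rn, s$reactions, dmin))
    }
  }
})

test_that("single-compartment covers coincide with the organization flag", {
  ## a SOR needs one compartment iff its minimal DO is closed and supports
  ## exactly the SOR, i.e. iff the minimal DO is an organization realising it
  for (name in c("mirna", "three_generator")) {
    net <- example_network(name)
    for (s in all_sors(net)$sors) {
      if (!length(s$reactions)) next
      dmin <- s$min_do
      direct <- setequal(supported_reactions(net, dmin), s$reactions) &&
        setequal(species_closure(net, dmin), dmin)
      expect_equal(s$is_organization, direct,
                   label = paste(name, paste(s$reactions, collapse = "+")))
    }
  }
})

test_that("the three-generator triple SOR needs three compartments", {
  ## separating A2 from B1, B3 and A1 while keeping each generator closed
  ## forces one compartment per generator
  net3 <- example_network("three_generator")
  sor <- c("R1", "R2", "R3")
  dmin <- min_do_of_sor(net3, sor)
  mcs <- create_mcs(net3, sor, dmin)
  cov <- get_min_compartments(net3, sor, mcs)
  expect_length(cov, 3)
  ## strict DO cover mode can only need at least as many compartments
  cov_do <- get_min_compartments(net3, sor, mcs, cover_do = TRUE,
                                 do_species = dmin)
  expect_gte(length(cov_do), length(cov))
})
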
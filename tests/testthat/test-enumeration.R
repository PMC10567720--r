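test_that("SOR enumeration reproduces the hand-derived micro-RNA sets", {
  net <- example_network("mirna")
  sors <- all_sors(net)
  expect_equal(sors$status, "complete")
  expect_same_sets(lapply(sors$sors, `[[`, "reactions"), mirna_sor_sets())
  ## the first solution maximizes cardinality; sizes never increase
  sizes <- vapply(sors$sors, function(s) length(s$reactions), 0)
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[1], 11)
  ## no inflow: the empty SOR is present and is an organization
  empty <- sors$sors[[which(sizes == 0)]]
  expect_true(empty$is_organization)
  ## min DO of a SOR is the union of its support closures
  for (s in sors$sors) {
    expect_setequal(s$min_do, min_do_of_sor(net, s$reactions))
  }
  expect_setequal(min_do_of_sor(net, c("r3", "r4", "r5", "r6")),
                  c("miR_gene", "TF2", "miR_gene_TF2", "miR", "Sink"))
  expect_length(min_do_of_sor(net, character(0)), 0)
  ## {r6} is ERC-closed but not self-maintaining: never a SOR
  expect_false("r6" %in% set_keys(lapply(sors$sors, `[[`, "reactions")))
})

test_that("3-generator minimal DOs and witness structure are consistent", {
  net3 <- example_network("three_generator")
  expect_setequal(min_do_of_sor(net3, "R1"), c("A1", "B1"))
  sors <- all_sors(net3)
  expect_equal(sors$status, "complete")
  ## MILP path equals the definition-level oracle exactly
  expect_same_sets(lapply(sors$sors, `[[`, "reactions"), oracle_sors(net3))
  ## each witness certifies its SOR
  N <- stoichiometric_matrix(net3)
  for (s in sors$sors) {
    expect_true(all(as.numeric(N %*% s$witness) >= -1e-7))
    expect_setequal(names(s$witness)[s$witness > 1e-7], s$reactions)
  }
})

test_that("degenerate networks enumerate correctly", {
  ## zero reactions: exactly one SOR, the empty one
  empty <- reaction_network()
  s <- all_sors(empty)
  expect_length(s$sors, 1)
  expect_length(s$sors[[1]]$reactions, 0)
  ## one species, no reactions: the DOs are {} and {s}
  one <- reaction_network(species = "X")
  d <- all_dos(one)
  expect_same_sets(lapply(d$dos, `[[`, "species"), list(character(0), "X"))
  ## inflow reactions are in every SOR (R_min)
  inet <- read_reaction_text(c("i: -> A", "d: A -> 0", "c: B -> B + A"))
  si <- all_sors(inet, annotate = FALSE)
  for (s in si$sors) expect_true("i" %in% s$reactions)
})

test_that("every SOR contains R_min and enumeration caps are flagged", {
  net <- example_network("mirna")
  capped <- all_sors(net, enumeration_config(max_solutions = 3), annotate = FALSE)
  expect_equal(capped$status, "truncated")
  expect_length(capped$sors, 3)
  ## R_min on random networks with inflows
  for (seed in 1:10) {
    rn <- random_network(5, 6, inflow_probability = 0.3, seed = seed)
    ercs <- create_ercs(rn)
    rmin <- unique(unlist(lapply(inflow_reactions(rn),
                                 function(r) ercs[[r]]$reactions)))
    sr <- all_sors(rn, annotate = FALSE)
    for (s in sr$sors) expect_true(all(rmin %in% s$reactions))
  }
})

test_that("DO enumeration agrees with its SOR-based reconstruction", {
  net <- example_network("mirna")
  dos <- all_dos(net)
  sors <- all_sors(net, annotate = FALSE)
  expect_same_sets(lapply(dos$dos, `[[`, "species"), dos_from_sors(net, sors))
  ## the smallest DO is empty (no inflow), the largest is the full set
  sizes <- vapply(dos$dos, function(d) length(d$species), 0)
  expect_equal(min(sizes), 0)
  expect_equal(max(sizes), 9)
  ## every DO-SOR pair is certified by its maximal compartments:
  ## MCs cover the DO and jointly support exactly the SOR
  for (d in dos$dos) {
    for (sor in d$sors) {
      mcs <- create_mcs(net, sor, d$species)
      expect_setequal(unique(unlist(mcs)), d$species)
      joint <- unique(unlist(lapply(mcs, function(mc) {
        supported_reactions(net, mc)
      })))
      expect_setequal(joint, sor)
    }
  }
})

test_that("genuine DOs require separable higher-order supports", {
  ## order <= 1 networks cannot separate any support: no genuine DOs
  for (seed in 1:12) {
    rn <- random_network(6, 8, max_order = 1, seed = seed)
    dr <- all_dos(rn)
    expect_false(any(vapply(dr$dos, `[[`, TRUE, "is_genuine")),
                 label = paste("seed", seed))
  }
  ## the DO organization flag matches the direct closed+self-maintaining test
  net <- example_network("mirna")
  for (d in all_dos(net)$dos) {
    expect_equal(d$is_organization, is_organization(net, d$species))
  }
})
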
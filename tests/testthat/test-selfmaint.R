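test_that("self-maintenance witnesses satisfy Nv >= 0 with exact support", {
  net <- example_network("mirna")
  ## r6 alone would deplete miR: no witness
  expect_null(self_maintaining_flux(net, "r6"))
  ## empty active set: the zero flux, nothing overproduced
  z <- self_maintaining_flux(net, character(0))
  expect_equal(unname(z$flux), rep(0, 11))
  expect_length(z$overproduced, 0)
  ## a working cycle
  w <- self_maintaining_flux(net, c("r7", "r8", "r10", "r11"))
  expect_false(is.null(w))
  expect_true(all(w$production >= -1e-7))
  active <- names(w$flux)[w$flux > 1e-7]
  expect_setequal(active, c("r7", "r8", "r10", "r11"))
  expect_true(all(w$flux[active] >= 1 - 1e-7))
  expect_true("Sink" %in% w$overproduced)
  ## 3-generator: a lone generator overproduces its product
  net3 <- example_network("three_generator")
  w3 <- self_maintaining_flux(net3, "R1")
  expect_setequal(w3$overproduced, "B1")
  expect_error(self_maintaining_flux(net, "nosuch"), "unknown reaction")
})

test_that("witness invariants hold across random networks", {
  for (seed in 1:20) {
    rn <- random_network(6, 7, seed = seed)
    N <- stoichiometric_matrix(rn)
    ids <- reaction_ids(rn)
    active <- sample(ids, sample(1:4, 1))
    w <- self_maintaining_flux(rn, active)
    if (is.null(w)) next
    expect_true(all(as.numeric(N %*% w$flux) >= -1e-7))
    expect_true(all(w$flux[active] >= 1 - 1e-7))
    expect_true(all(w$flux[setdiff(ids, active)] == 0))
    expect_setequal(w$overproduced,
                    rn$species[as.numeric(N %*% w$flux) > 1e-7])
  }
})

test_that("max_overproduced is the union over witnesses, order-independent", {
  net3 <- example_network("three_generator")
  expect_setequal(max_overproduced(net3, "R1"), "B1")
  expect_length(max_overproduced(net3, character(0)), 0)
  net <- example_network("mirna")
  ## with free choice of v7 > v8 and v10 > v11 all three accumulate
  expect_setequal(max_overproduced(net, c("r7", "r8", "r10", "r11")),
                  c("Sink", "TF1_mRNA", "TF1"))
  expect_error(max_overproduced(net, "r6"), "no self-maintaining flux")
  ## probing order cannot matter: result is a union of per-species probes,
  ## and contains the overproduced set of any single witness
  w <- self_maintaining_flux(net, c("r3", "r4", "r5", "r6"))
  expect_true(all(w$overproduced %in%
                    max_overproduced(net, c("r3", "r4", "r5", "r6"))))
})

test_that("distribute_flux splits by support counts and sums exactly", {
  net <- example_network("mirna")
  sor <- c("r3", "r4", "r5", "r6", "r7", "r8", "r10", "r11")
  w <- self_maintaining_flux(net, sor)
  ## one compartment with every support: identity
  one <- distribute_flux(net, w$flux, list(net$species))
  expect_equal(one[[1]], w$flux)
  ## a 3-compartment split of the same SOR
  comps <- list(
    c("Signal", "Sink", "TF2", "TF1_mRNA", "TF1"),
    c("Sink", "miR_gene", "TF2", "miR_gene_TF2", "miR"),
    c("Sink", "TF2", "miR", "TF1")
  )
  parts <- distribute_flux(net, w$flux, comps)
  expect_length(parts, 3)
  ## r6 (miR -> Sink) is supported by compartments 2 and 3: split in half
  expect_equal(parts[[2]][["r6"]], w$flux[["r6"]] / 2)
  expect_equal(parts[[3]][["r6"]], w$flux[["r6"]] / 2)
  expect_equal(parts[[1]][["r6"]], 0)
  ## outputs sum exactly to the input
  expect_equal(Reduce(`+`, parts), w$flux)
  ## each part is positive exactly on the reactions its compartment supports
  for (i in seq_along(parts)) {
    pos <- names(parts[[i]])[parts[[i]] > 0]
    supp_ok <- vapply(pos, function(r) {
      all(reaction_support(net, r) %in% comps[[i]])
    }, TRUE)
    expect_true(all(supp_ok))
  }
  ## uncovered active reaction is an error
  expect_error(distribute_flux(net, w$flux, comps[3]), "no compartment")
})
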
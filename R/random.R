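## ---------------------------------------------------------------------------
## Seeded random networks and definition-level brute-force oracles
##
## The oracles below work straight from the definitions (closedness via
## subset scans, self-maintenance via one LP per candidate) and share no
## code with the MILP enumeration path; they exist to property-test it.
## ---------------------------------------------------------------------------

#' Generate a random reaction network
#'
#' Draws `n_reactions` reactions over species `S1..Sn` with reaction
#' orders (max of support and product size) bounded by `max_order`.
#' Support sizes are biased so that roughly 20% of non-inflow reactions
#' have order two or more -- mirroring the prevalence of higher-order
#' reactions in curated biochemical models, which is what makes genuine
#' DOs possible at all. With probability `catalytic_probability` a support
#' species is copied into the products (a catalyst). Duplicate reactions
#' are redrawn (a bounded number of times). The same seed always yields
#' the same network; the caller's RNG state is left untouched.
#'
#' @param n_species number of species (>= 1)
#' @param n_reactions number of reactions
#' @param max_order maximal size of support and of product set (>= 1)
#' @param inflow_probability probability of an empty support (an inflow)
#' @param outflow_probability probability of an empty product side
#' @param catalytic_probability probability that a reaction is catalytic
#' @param seed integer seed
#' @return a `reaction_network` with species `S1..Sn` (all listed, even if
#'   unused) and reactions `g1..gm`
#' @export
random_network <- function(n_species, n_reactions, max_order = 2,
                           inflow_probability = 0.05,
                           outflow_probability = 0.15,
                           catalytic_probability = 0.3,
                           seed = 1) {
  stopifnot(n_species >= 1, n_reactions >= 0, max_order >= 1,
            inflow_probability >= 0, inflow_probability <= 1,
            catalytic_probability >= 0, catalytic_probability <= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  species <- paste0("S", seq_len(n_species))
  draw_side <- function(size) {
    if (size == 0L) return(NULL)
    sp <- sample(species, min(size, n_species))
    coef <- sample(1:2, length(sp), replace = TRUE, prob = c(0.85, 0.15))
    stats::setNames(coef, sp)
  }
  reactions <- list()
  seen <- character(0)
  for (j in seq_len(n_reactions)) {
    for (try in 1:25) {
      s_size <- if (stats::runif(1) < inflow_probability) 0L
        else if (max_order >= 2 && stats::runif(1) < 0.2) sample(2:max_order, 1)
        else 1L
      p_size <- if (s_size > 0L && stats::runif(1) < outflow_probability) 0L
        else sample(seq_len(max_order), 1)
      reactants <- draw_side(s_size)
      products <- draw_side(p_size)
      if (!is.null(reactants) && !is.null(products) &&
          stats::runif(1) < catalytic_probability) {
        cat_sp <- names(reactants)[1]
        products <- products[setdiff(names(products), cat_sp)]
        products <- c(stats::setNames(reactants[cat_sp], cat_sp), products)
        ## keep the product-side order within max_order
        if (length(products) > max_order) products <- products[seq_len(max_order)]
      }
      key <- paste(.side_str(.coef_vec(reactants, "x")), "->",
                   .side_str(.coef_vec(products, "x")))
      if (!(key %in% seen)) { seen <- c(seen, key); break }
    }
    reactions[[j]] <- list(id = paste0("g", j), reactants = reactants,
                           products = products)
  }
  reaction_network(reactions, species = species)
}

#' Brute-force enumeration of all SORs
#'
#' Independent oracle for [all_sors()]: scans all `2^m` reaction subsets
#' and keeps those that (i) equal the union of the ERCs of their members,
#' (ii) contain every inflow reaction, and (iii) admit a self-maintaining
#' flux with support exactly the subset.
#'
#' @param net a `reaction_network` with at most 14 reactions
#' @param big_m flux upper bound used in the feasibility LPs
#' @return list of character vectors (reaction ids), one per SOR
#' @export
oracle_sors <- function(net, big_m = 10000) {
  m <- n_reactions(net)
  if (m > 14) stop("oracle_sors: refusing m > 14 (2^m scan)")
  ids <- reaction_ids(net)
  ercs <- create_ercs(net)
  erc_mask <- vapply(ids, function(r) {
    .mask(match(ercs[[r]]$reactions, ids))
  }, 0)
  inflow_mask <- .mask(match(inflow_reactions(net), ids))
  out <- list()
  for (R in 0:(2^m - 1)) {
    if (bitwAnd(R, inflow_mask) != inflow_mask) next
    members <- which(bitwAnd(R, 2^(seq_len(m) - 1)) > 0)
    u <- 0
    for (j in members) u <- bitwOr(u, erc_mask[j])
    if (u != R) next
    if (!is.null(self_maintaining_flux(net, ids[members], big_m))) {
      out[[length(out) + 1L]] <- ids[members]
    }
  }
  out
}

.mask <- function(idx) if (!length(idx)) 0 else sum(2^(idx - 1))

#' Brute-force enumeration of all maximal compartments
#'
#' Independent oracle for [create_mcs()]: scans all subsets of the DO and
#' keeps the maximal ones that are closed and support only reactions of
#' the SOR.
#'
#' @param net a `reaction_network`
#' @param sor character vector of reaction ids
#' @param do_species character vector of species ids (at most 14)
#' @return list of species-id vectors, maximal, none a subset of another
#' @export
oracle_mcs <- function(net, sor, do_species) {
  d <- length(do_species)
  if (d > 14) stop("oracle_mcs: refusing |DO| > 14 (2^n scan)")
  valid <- list()
  for (S in 0:(2^d - 1)) {
    sub <- do_species[bitwAnd(S, 2^(seq_len(d) - 1)) > 0]
    supp <- supported_reactions(net, sub)
    if (!all(supp %in% sor)) next
    if (!setequal(species_closure(net, sub), sub)) next
    valid[[length(valid) + 1L]] <- sub
  }
  keep <- vapply(seq_along(valid), function(i) {
    !any(vapply(seq_along(valid), function(j) {
      i != j && length(valid[[i]]) < length(valid[[j]]) &&
        all(valid[[i]] %in% valid[[j]])
    }, TRUE))
  }, TRUE)
  valid[keep]
}

#' Brute-force enumeration of all DOs
#'
#' Independent oracle for [all_dos()]: a species set `D` is kept when some
#' brute-forced SOR `R` has all its species inside `D` and the maximal
#' closed subsets of `D` supporting only reactions of `R` cover `D` and
#' jointly support exactly `R`.
#'
#' @param net a `reaction_network` with at most 10 species and 12 reactions
#' @param big_m flux upper bound for the feasibility LPs
#' @return list of species-id vectors, one per DO
#' @export
oracle_dos <- function(net, big_m = 10000) {
  n <- n_species(net)
  m <- n_reactions(net)
  if (n > 10 || m > 12) stop("oracle_dos: refusing n > 10 or m > 12")
  ids <- reaction_ids(net)
  sors <- oracle_sors(net, big_m)
  sor_masks <- vapply(sors, function(s) .mask(match(s, ids)), 0)
  ## per species-subset: supported reaction mask and closedness
  nsub <- 2^n
  spbit <- 2^(seq_len(n) - 1)
  supp_mask <- numeric(nsub)
  closed <- logical(nsub)
  for (S in 0:(nsub - 1)) {
    sub <- net$species[bitwAnd(S, spbit) > 0]
    sr <- supported_reactions(net, sub)
    supp_mask[S + 1] <- .mask(match(sr, ids))
    closed[S + 1] <- setequal(species_closure(net, sub), sub)
  }
  sor_species_mask <- vapply(sors, function(s) {
    .mask(match(species_of_sor(net, s), net$species))
  }, 0)
  all_masks <- 0:(nsub - 1)
  out <- list()
  for (D in all_masks) {
    is_do <- FALSE
    for (k in seq_along(sors)) {
      if (bitwAnd(sor_species_mask[k], D) != sor_species_mask[k]) next
      ## closed subsets of D supporting only reactions of the SOR
      inside <- all_masks[bitwAnd(all_masks, D) == all_masks]
      ok <- closed[inside + 1] &
        bitwAnd(supp_mask[inside + 1], sor_masks[k]) == supp_mask[inside + 1]
      cand <- inside[ok]
      if (!length(cand)) next
      cover <- Reduce(bitwOr, cand, 0)
      joint <- Reduce(bitwOr, supp_mask[cand + 1], 0)
      if (cover == D && joint == sor_masks[k]) { is_do <- TRUE; break }
    }
    if (is_do) {
      out[[length(out) + 1L]] <- net$species[bitwAnd(D, spbit) > 0]
    }
  }
  out
}

#' Organization test for a species set
#'
#' A species set is an organization (in the classic, single-compartment
#' sense) when it is closed and the set of all reactions it supports
#' admits a self-maintaining flux.
#'
#' @param net a `reaction_network`
#' @param species character vector of species ids
#' @param big_m flux upper bound
#' @return `TRUE`/`FALSE`
#' @export
is_organization <- function(net, species, big_m = 10000) {
  if (!setequal(species_closure(net, species), species)) return(FALSE)
  !is.null(self_maintaining_flux(net, supported_reactions(net, species), big_m))
}
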
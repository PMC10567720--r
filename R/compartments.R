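## ---------------------------------------------------------------------------
## Maximal compartments and minimal compartmentalizations
## ---------------------------------------------------------------------------

#' Species taking part in a SOR
#'
#' @param net a `reaction_network`
#' @param reactions character vector of reaction ids
#' @return union of supports and products of the reactions, in network
#'   species order; empty for the empty set
#' @export
species_of_sor <- function(net, reactions) {
  if (!length(reactions)) return(character(0))
  out <- unique(unlist(lapply(reactions, function(r) {
    c(reaction_support(net, r), reaction_products(net, r))
  })))
  net$species[net$species %in% out]
}

#' All maximal compartments of a DO-SOR pair
#'
#' A compartment of a DO-SOR pair is a species subset of the DO that is
#' closed and supports only reactions of the SOR; a maximal compartment
#' (MC) is one not strictly contained in another. Starting from the full
#' DO species set, every candidate supporting a violating reaction -- a
#' reaction outside the SOR, or any supported reaction whose products
#' leave the candidate (a closure violation) -- is split into one child
#' per support species, each child missing exactly that species. A
#' candidate supporting a violating inflow reaction (empty support) cannot
#' be repaired and is discarded. Subset candidates are pruned throughout;
#' the surviving candidates are the unique maximal compartments.
#'
#' @param net a `reaction_network`
#' @param sor character vector of reaction ids (the SOR)
#' @param do_species character vector of species ids (the DO); must contain
#'   support and products of every SOR reaction
#' @return list of character vectors (each in network species order), no
#'   one a subset of another
#' @export
#' @examples
#' net <- example_network("mirna")
#' sor <- c("r3", "r4", "r5", "r6", "r7", "r8", "r10", "r11")
#' mcs <- create_mcs(net, sor, net$species)
#' length(mcs)  # 3
create_mcs <- function(net, sor, do_species) {
  sor <- as.character(sor)
  do_species <- unique(as.character(do_species))
  need <- species_of_sor(net, sor)
  if (!all(need %in% do_species)) {
    stop("do_species must contain every species of the SOR; missing: ",
         paste(setdiff(need, do_species), collapse = ", "))
  }
  key <- function(s) paste(sort(s), collapse = "\r")
  finals <- list()
  final_keys <- character(0)
  pending <- list(do_species)
  seen <- key(do_species)
  is_subset_of_any <- function(s, sets) {
    for (t in sets) if (all(s %in% t)) return(TRUE)
    FALSE
  }
  while (length(pending)) {
    cand <- pending[[length(pending)]]
    pending[[length(pending)]] <- NULL
    if (is_subset_of_any(cand, finals)) next
    ## find a violating reaction: supported but outside the SOR, or
    ## supported with products escaping the candidate
    viol <- NULL
    for (r in net$reactions) {
      if (all(names(r$reactants) %in% cand)) {
        outside_sor <- !(r$id %in% sor)
        escapes <- !all(names(r$products) %in% cand)
        if (outside_sor || escapes) { viol <- r; break }
      }
    }
    if (is.null(viol)) {
      finals[[length(finals) + 1L]] <- cand
      final_keys <- c(final_keys, key(cand))
      next
    }
    supp <- names(viol$reactants)
    if (!length(supp)) next  # inflow violation: candidate is unrepairable
    for (s in supp) {
      child <- setdiff(cand, s)
      k <- key(child)
      if (!(k %in% seen)) {
        seen <- c(seen, k)
        pending[[length(pending) + 1L]] <- child
      }
    }
  }
  ## delete proper subsets among the survivors
  keep <- vapply(seq_along(finals), function(i) {
    !any(vapply(seq_along(finals), function(j) {
      i != j && all(finals[[i]] %in% finals[[j]]) &&
        length(finals[[i]]) < length(finals[[j]])
    }, TRUE))
  }, TRUE)
  finals <- finals[keep]
  lapply(finals, function(s) net$species[net$species %in% s])
}

#' Minimal compartmentalization of a SOR (set cover)
#'
#' Selects a minimum-cardinality subset of the maximal compartments such
#' that every species of `species_of_sor(net, sor)` lies in a chosen
#' compartment and the support of every SOR reaction is contained in a
#' chosen compartment -- an exact set-cover integer program. The optimal
#' size is unique; the chosen compartments need not be.
#'
#' With `cover_do = TRUE` the cover is additionally required to contain
#' every species of `do_species` (the strict reading under which the
#' compartment union reproduces the whole DO, including non-reacting
#' species).
#'
#' @param net a `reaction_network`
#' @param sor character vector of reaction ids
#' @param mcs list of species-id vectors, typically from [create_mcs()]
#' @param cover_do cover all DO species instead of only `species(SOR)`
#' @param do_species required when `cover_do = TRUE`
#' @return list of chosen compartments (a subset of `mcs`); `list()` for
#'   an empty SOR with nothing to cover
#' @export
#' @examples
#' net <- example_network("mirna")
#' sor <- c("r3", "r4", "r5", "r6", "r7", "r8", "r10", "r11")
#' mcs <- create_mcs(net, sor, net$species)
#' length(get_min_compartments(net, sor, mcs))  # 2
get_min_compartments <- function(net, sor, mcs, cover_do = FALSE,
                                 do_species = NULL) {
  cover_species <- species_of_sor(net, sor)
  if (cover_do) {
    if (is.null(do_species)) stop("cover_do = TRUE needs do_species")
    cover_species <- unique(c(cover_species, do_species))
  }
  if (!length(cover_species) && !length(sor)) return(list())
  k <- length(mcs)
  rows <- list(); dirs <- character(); rhss <- numeric()
  for (s in cover_species) {
    row <- as.numeric(vapply(mcs, function(mc) s %in% mc, TRUE))
    rows[[length(rows) + 1L]] <- row; dirs <- c(dirs, ">="); rhss <- c(rhss, 1)
  }
  for (r in sor) {
    supp <- reaction_support(net, r)
    row <- as.numeric(vapply(mcs, function(mc) all(supp %in% mc), TRUE))
    rows[[length(rows) + 1L]] <- row; dirs <- c(dirs, ">="); rhss <- c(rhss, 1)
  }
  if (any(vapply(rows, function(r) all(r == 0), TRUE))) {
    stop("invalid DO-SOR pair: no compartment covers some species or reaction")
  }
  for (j in seq_len(k)) {
    row <- numeric(k); row[j] <- 1
    rows[[length(rows) + 1L]] <- row; dirs <- c(dirs, "<="); rhss <- c(rhss, 1)
  }
  A <- do.call(rbind, rows)
  sol <- .milp_solve(rep(1, k), A, dirs, rhss, binary_idx = seq_len(k),
                     maximize = FALSE)
  if (sol$status != "optimal") {
    stop("invalid DO-SOR pair: set cover infeasible")
  }
  mcs[round(sol$x) == 1]
}
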
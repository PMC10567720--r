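## ---------------------------------------------------------------------------
## Self-maintenance LPs and flux distribution
## ---------------------------------------------------------------------------

#' Self-maintaining flux witness for a reaction set
#'
#' Tests whether the network admits a flux vector `v >= 0` with support
#' exactly `active` and non-negative net production of every species
#' (`N v >= 0`). Strict positivity of active fluxes is encoded as
#' `1 <= v_j <= big_m` (harmless by scale invariance of `N v >= 0`);
#' inactive reactions are fixed to zero.
#'
#' @param net a `reaction_network`
#' @param active character vector of reaction ids (the prospective support)
#' @param big_m upper flux bound, default 10000
#' @return `NULL` when no such flux exists; otherwise a certificate: a list
#'   with `flux` (named vector over all reactions), `production` (`N v`
#'   per species) and `overproduced` (species with production above
#'   tolerance `1e-7`)
#' @export
#' @examples
#' net <- example_network("mirna")
#' self_maintaining_flux(net, c("r7", "r8", "r10", "r11"))$overproduced
#' is.null(self_maintaining_flux(net, "r6"))  # miR would be depleted
self_maintaining_flux <- function(net, active, big_m = 10000) {
  active <- unique(as.character(active))
  unknown <- setdiff(active, reaction_ids(net))
  if (length(unknown)) stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  N <- stoichiometric_matrix(net)
  if (length(active) == 0L) {
    v <- stats::setNames(numeric(n_reactions(net)), reaction_ids(net))
    prod <- stats::setNames(numeric(n_species(net)), net$species)
    return(list(flux = v, production = prod, overproduced = character(0)))
  }
  Na <- N[, active, drop = FALSE]
  k <- length(active)
  A <- rbind(Na,                       # N v >= 0
             diag(k),                  # v_j >= 1
             diag(k))                  # v_j <= big_m
  dir <- c(rep(">=", nrow(Na)), rep(">=", k), rep("<=", k))
  rhs <- c(rep(0, nrow(Na)), rep(1, k), rep(big_m, k))
  sol <- .lp_solve(rep(0, k), A, dir, rhs, maximize = FALSE)
  if (sol$status != "optimal") return(NULL)
  v <- stats::setNames(numeric(n_reactions(net)), reaction_ids(net))
  v[active] <- sol$x
  production <- as.numeric(N %*% v)
  names(production) <- net$species
  list(flux = v, production = production,
       overproduced = net$species[production > 1e-7])
}

#' Largest overproducible species set of a reaction set
#'
#' Among all self-maintaining fluxes with support exactly `active` there is
#' a unique largest set of species with strictly positive net production
#' (the union over all witnesses). It is computed by probing each species
#' with one feasibility LP carrying the extra constraint `(N v)_i >= 1`
#' and collecting the achievable species; the result does not depend on
#' the probing order.
#'
#' @inheritParams self_maintaining_flux
#' @return character vector of species ids (network order)
#' @export
#' @examples
#' net <- example_network("three_generator")
#' max_overproduced(net, "R1")  # only B1 can be overproduced
max_overproduced <- function(net, active, big_m = 10000) {
  active <- unique(as.character(active))
  if (length(active) == 0L) return(character(0))
  base <- self_maintaining_flux(net, active, big_m)
  if (is.null(base)) {
    stop("reaction set admits no self-maintaining flux; overproduction undefined")
  }
  N <- stoichiometric_matrix(net)
  Na <- N[, active, drop = FALSE]
  k <- length(active)
  A0 <- rbind(Na, diag(k), diag(k))
  dir0 <- c(rep(">=", nrow(Na)), rep(">=", k), rep("<=", k))
  rhs0 <- c(rep(0, nrow(Na)), rep(1, k), rep(big_m, k))
  ok <- vapply(seq_along(net$species), function(i) {
    sol <- .lp_solve(rep(0, k),
                     rbind(A0, Na[i, ]),
                     c(dir0, ">="),
                     c(rhs0, 1),
                     maximize = FALSE)
    sol$status == "optimal"
  }, TRUE)
  net$species[ok]
}

#' Distribute a flux over compartments
#'
#' Splits a flux vector with support in a reaction set `R` into
#' per-compartment fluxes: reaction `r_j` receives `v_j / l(j)` in each of
#' the `l(j)` compartments that support it and zero elsewhere. Each output
#' is a feasible flux with respect to its compartment restricted to `R`,
#' and the outputs sum exactly to the input.
#'
#' @param net a `reaction_network`
#' @param flux named numeric vector over (a subset of) the reaction ids;
#'   entries above `1e-7` count as active
#' @param compartments list of species-id vectors
#' @return list of named flux vectors, one per compartment, in input order
#' @export
distribute_flux <- function(net, flux, compartments) {
  ids <- reaction_ids(net)
  v <- stats::setNames(numeric(length(ids)), ids)
  v[names(flux)] <- flux
  active <- ids[v > 1e-7]
  supports <- lapply(compartments, function(S) {
    vapply(active, function(r) all(reaction_support(net, r) %in% S), TRUE)
  })
  l_j <- Reduce(`+`, lapply(supports, as.integer), rep(0L, length(active)))
  if (any(l_j == 0L)) {
    stop("active reaction(s) supported by no compartment: ",
         paste(active[l_j == 0L], collapse = ", "))
  }
  lapply(supports, function(supp) {
    out <- stats::setNames(numeric(length(ids)), ids)
    out[active] <- ifelse(supp, v[active] / l_j, 0)
    out
  })
}
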
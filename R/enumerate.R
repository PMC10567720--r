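## ---------------------------------------------------------------------------
## Enumeration of all SORs and all DOs by MILP with integer cuts
## ---------------------------------------------------------------------------

#' Enumeration settings
#'
#' @param solver name of a registered solver backend (see
#'   [solver_backend()]); default `"simplex_bb"`
#' @param big_m coupling constant `c` in `b_j * c >= v_j >= b_j`, tying the
#'   binary activity variables to strictly positive fluxes; default 10000
#' @param max_solutions cap on the number of enumerated solutions;
#'   default 50000
#' @param time_limit wall-clock limit in seconds for one enumeration
#'   (`Inf` = none); when hit, the partial result is flagged
#' @param tol numerical tolerance used for positivity/feasibility checks
#' @return a list of class `enumeration_config`
#' @export
enumeration_config <- function(solver = "simplex_bb", big_m = 10000,
                               max_solutions = 50000, time_limit = Inf,
                               tol = 1e-7) {
  stopifnot(big_m >= 1, max_solutions >= 1)
  structure(list(solver = solver, big_m = big_m,
                 max_solutions = max_solutions,
                 time_limit = time_limit, tol = tol),
            class = "enumeration_config")
}

## Build the shared constraint block of the SOR program over variables
## [v_1..v_m, b_1..b_m]:
##   N v >= 0                   (self-maintenance)
##   b_j = b_k  within an ERC equality class
##   b_j >= b_k for Hasse edges of the reduced ERC containment graph
##   b_j = 1 for inflow reactions
##   big_m * b_j - v_j >= 0,  v_j - b_j >= 0   (coupling)
##   b_j <= 1
.sor_constraints <- function(net, graph, big_m) {
  m <- n_reactions(net)
  ids <- reaction_ids(net)
  N <- stoichiometric_matrix(net)
  nvar <- 2L * m
  vcol <- function(j) j
  bcol <- function(j) m + j
  rows <- list(); dirs <- character(); rhss <- numeric()
  add <- function(row, d, r) {
    rows[[length(rows) + 1L]] <<- row
    dirs[length(dirs) + 1L] <<- d
    rhss[length(rhss) + 1L] <<- r
  }
  if (n_species(net) > 0 && m > 0) {
    for (i in seq_len(n_species(net))) {
      row <- numeric(nvar); row[seq_len(m)] <- N[i, ]
      add(row, ">=", 0)
    }
  }
  ## reaction closure on the reduced graph: equality within classes,
  ## one inequality per reduced containment edge
  reps <- integer(length(graph$classes))
  for (ci in seq_along(graph$classes)) {
    members <- match(graph$classes[[ci]], ids)
    reps[ci] <- members[1]
    for (j in members[-1]) {
      row <- numeric(nvar); row[bcol(j)] <- 1; row[bcol(members[1])] <- -1
      add(row, "==", 0)
    }
  }
  if (nrow(graph$edges)) {
    for (ei in seq_len(nrow(graph$edges))) {
      a <- reps[graph$edges[ei, 1]]; b <- reps[graph$edges[ei, 2]]
      ## ERC(b) strictly inside ERC(a): activating a activates b
      row <- numeric(nvar); row[bcol(b)] <- 1; row[bcol(a)] <- -1
      add(row, ">=", 0)
    }
  }
  for (r in inflow_reactions(net)) {
    row <- numeric(nvar); row[bcol(match(r, ids))] <- 1
    add(row, "==", 1)
  }
  for (j in seq_len(m)) {
    row <- numeric(nvar); row[bcol(j)] <- big_m; row[vcol(j)] <- -1
    add(row, ">=", 0)
    row <- numeric(nvar); row[vcol(j)] <- 1; row[bcol(j)] <- -1
    add(row, ">=", 0)
    row <- numeric(nvar); row[bcol(j)] <- 1
    add(row, "<=", 1)
  }
  list(A = do.call(rbind, rows), dir = dirs, rhs = rhss, nvar = nvar)
}

#' Enumerate all sets of organizational reactions (SORs)
#'
#' A reaction set `R` is a SOR when it is closed under elementary reaction
#' closures (`R` equals the union of the ERCs of its members) and admits a
#' flux `v` with support exactly `R` and `N v >= 0`. The largest SOR is
#' found first by a mixed-integer program over `(v, b)` maximizing
#' `sum(b)`; the remaining SORs follow by adding one integer cut per
#' solution, so solutions arrive in non-increasing size. Every SOR
#' contains `R_min`, the union of the ERCs of the inflow reactions; for a
#' network without inflow the empty set is a SOR and arrives last.
#'
#' @param net a `reaction_network`
#' @param config an [enumeration_config()]
#' @param annotate when `TRUE` (default) each SOR carries its minimal DO,
#'   overproduced species, minimal compartmentalization size and
#'   organization flag; `FALSE` skips these for speed
#' @return an object of class `sor_set`: a list with `sors` (list of SOR
#'   records), `status` (`"complete"`, `"truncated"` or `"timeout"`) and
#'   the `network`. Each SOR record has `reactions`, `witness` (named
#'   flux), and with `annotate` also `min_do`, `overproduced`,
#'   `min_compartments`, `n_compartments` and `is_organization`.
#' @export
#' @examples
#' sors <- all_sors(example_network("mirna"))
#' length(sors$sors)  # 8
all_sors <- function(net, config = enumeration_config(), annotate = TRUE) {
  m <- n_reactions(net)
  ids <- reaction_ids(net)
  if (m == 0L) {
    sors <- list(.sor_record(net, character(0), stats::setNames(numeric(0), character(0)),
                             annotate, config$big_m))
    return(structure(list(sors = sors, status = "complete", network = net),
                     class = "sor_set"))
  }
  graph <- erc_graph(create_ercs(net))
  cons <- .sor_constraints(net, graph, config$big_m)
  obj <- c(numeric(m), rep(1, m))
  backend <- solver_backend(config$solver)
  res <- backend$enumerate(obj, cons$A, cons$dir, cons$rhs,
                           binary_idx = m + seq_len(m),
                           cut_idx = m + seq_len(m),
                           maximize = TRUE,
                           max_solutions = config$max_solutions,
                           time_limit = config$time_limit)
  sors <- lapply(res$solutions, function(sol) {
    b <- round(sol$x[m + seq_len(m)])
    active <- ids[b == 1]
    witness <- stats::setNames(sol$x[seq_len(m)], ids)
    witness[b == 0] <- 0
    .sor_record(net, active, witness, annotate, config$big_m)
  })
  structure(list(sors = sors, status = res$status, network = net),
            class = "sor_set")
}

.sor_record <- function(net, reactions, witness, annotate, big_m) {
  rec <- list(reactions = reactions, witness = witness)
  if (annotate) {
    rec$min_do <- min_do_of_sor(net, reactions)
    rec$overproduced <- if (length(reactions)) {
      max_overproduced(net, reactions, big_m)
    } else {
      character(0)
    }
    mcs <- create_mcs(net, reactions, rec$min_do)
    mincov <- get_min_compartments(net, reactions, mcs)
    rec$min_compartments <- mincov
    rec$n_compartments <- length(mincov)
    rec$is_organization <- length(mincov) <= 1L
  }
  class(rec) <- "sor"
  rec
}

#' @export
print.sor_set <- function(x, ...) {
  cat("sor_set:", length(x$sors), "SORs (", x$status, ")\n")
  for (s in x$sors) {
    cat("  {", paste(s$reactions, collapse = ", "), "}",
        if (!is.null(s$is_organization) && s$is_organization) " [organization]" else "",
        "\n", sep = "")
  }
  invisible(x)
}

#' Minimal DO of a SOR
#'
#' The smallest species set on which a SOR can run: the union of the
#' closures of the supports of its reactions (one closed compartment per
#' reaction). Every other DO realising the SOR adds only non-reacting
#' species.
#'
#' @param net a `reaction_network`
#' @param reactions character vector of reaction ids (a SOR)
#' @return character vector of species ids in network order; empty for the
#'   empty SOR
#' @export
min_do_of_sor <- function(net, reactions) {
  if (!length(reactions)) return(character(0))
  out <- unique(unlist(lapply(reactions, function(r) {
    species_closure(net, reaction_support(net, r))
  })))
  net$species[net$species %in% out]
}

#' Enumerate all distributed organizations (DOs)
#'
#' A species set `D` is a DO when it is a union of closed compartments
#' whose per-compartment feasible fluxes sum to a flux with `N v >= 0`.
#' The program extends the SOR program by one binary `e_i` per species:
#' active reactions force their participating species into `D`
#' (`e_i >= b_j`), and a present species forces every reaction supported
#' by its single-species closure to be active (`b_j >= e_i`). DO-SOR
#' pairs are enumerated over the concatenated `(b, e)` vector with integer
#' cuts, largest `D` first, then projected onto distinct species sets;
#' the DO-SOR map is retained.
#'
#' @inheritParams all_sors
#' @return an object of class `do_set`: `dos` is a list of records with
#'   `species`, `sors` (list of reaction-id vectors realisable on the
#'   set), `is_organization` (the set is closed and self-maintaining in
#'   the classic sense) and `is_genuine` (a DO with no single-compartment
#'   realisation); `n_pairs` counts the enumerated DO-SOR pairs; `status`
#'   as in [all_sors()]
#' @export
#' @examples
#' dos <- all_dos(example_network("mirna"))
#' c(length(dos$dos), sum(vapply(dos$dos, `[[`, TRUE, "is_genuine")))  # 17, 6
all_dos <- function(net, config = enumeration_config()) {
  m <- n_reactions(net)
  n <- n_species(net)
  ids <- reaction_ids(net)
  if (m == 0L && n == 0L) {
    dos <- list(.do_record(net, character(0), list(character(0))))
    return(structure(list(dos = dos, n_pairs = 1L, status = "complete",
                          network = net), class = "do_set"))
  }
  graph <- if (m > 0) erc_graph(create_ercs(net)) else NULL
  base <- if (m > 0) {
    .sor_constraints(net, graph, config$big_m)
  } else {
    list(A = matrix(0, 0, 0), dir = character(0), rhs = numeric(0), nvar = 0L)
  }
  nvar <- 2L * m + n
  pad <- function(row) c(row, numeric(n))
  rows <- if (nrow(base$A)) {
    lapply(seq_len(nrow(base$A)), function(i) pad(base$A[i, ]))
  } else {
    list()
  }
  dirs <- base$dir; rhss <- base$rhs
  add <- function(row, d, r) {
    rows[[length(rows) + 1L]] <<- row
    dirs[length(dirs) + 1L] <<- d
    rhss[length(rhss) + 1L] <<- r
  }
  ecol <- function(i) 2L * m + i
  bcol <- function(j) m + j
  ## species closure: e_i = 1 activates every reaction supported by
  ## clos({s_i}); one row per ERC equality class (b is tied within a class)
  if (m > 0 && n > 0) {
    reps <- vapply(graph$classes, function(cl) match(cl[1], ids), 0L)
    for (i in seq_len(n)) {
      clos_i <- species_closure(net, net$species[i])
      supp <- supported_reactions(net, clos_i)
      cls <- unique(graph$class_of[supp])
      for (ci in cls) {
        row <- numeric(nvar); row[bcol(reps[ci])] <- 1; row[ecol(i)] <- -1
        add(row, ">=", 0)
      }
    }
    ## coupling e_i >= b_j for species taking part in reaction j
    for (j in seq_len(m)) {
      r <- net$reactions[[j]]
      for (s in union(names(r$reactants), names(r$products))) {
        row <- numeric(nvar)
        row[ecol(match(s, net$species))] <- 1; row[bcol(j)] <- -1
        add(row, ">=", 0)
      }
    }
  }
  for (i in seq_len(n)) {
    row <- numeric(nvar); row[ecol(i)] <- 1
    add(row, "<=", 1)
  }
  A <- do.call(rbind, rows)
  obj <- c(numeric(2L * m), rep(1, n))
  backend <- solver_backend(config$solver)
  res <- backend$enumerate(obj, A, dirs, rhss,
                           binary_idx = c(m + seq_len(m), 2L * m + seq_len(n)),
                           cut_idx = c(m + seq_len(m), 2L * m + seq_len(n)),
                           maximize = TRUE,
                           max_solutions = config$max_solutions,
                           time_limit = config$time_limit)
  ## project DO-SOR pairs onto distinct species sets
  pairs <- lapply(res$solutions, function(sol) {
    b <- round(sol$x[m + seq_len(m)])
    e <- round(sol$x[2L * m + seq_len(n)])
    list(species = net$species[e == 1], sor = ids[b == 1])
  })
  keys <- vapply(pairs, function(p) paste(p$species, collapse = "\r"), "")
  dos <- lapply(unique(keys), function(k) {
    sel <- pairs[keys == k]
    .do_record(net, sel[[1]]$species, lapply(sel, `[[`, "sor"))
  })
  structure(list(dos = dos, n_pairs = length(pairs), status = res$status,
                 network = net), class = "do_set")
}

.do_record <- function(net, species, sors) {
  clos <- species_closure(net, species)
  is_org <- FALSE
  if (setequal(clos, species)) {
    ## classic organization: closed and self-maintaining, i.e. the full
    ## supported reaction set admits a witness flux
    is_org <- !is.null(self_maintaining_flux(net, supported_reactions(net, species)))
  }
  structure(list(species = species, sors = sors,
                 is_organization = is_org, is_genuine = !is_org),
            class = "do")
}

#' @export
print.do_set <- function(x, ...) {
  ng <- sum(vapply(x$dos, `[[`, TRUE, "is_genuine"))
  cat("do_set:", length(x$dos), "DOs,", ng, "genuine (", x$status, "),",
      x$n_pairs, "DO-SOR pairs\n")
  invisible(x)
}

#' Recover the DOs from an enumerated SOR set
#'
#' Alternative route to [all_dos()]: every DO is a minimal DO of some SOR
#' extended by non-reacting species whose single-species closures stay
#' inside the SOR. Intended as a cross-check of the direct DO program.
#'
#' @param net a `reaction_network`
#' @param sor_set result of [all_sors()]
#' @return character vector keys are not returned; a list of species-id
#'   vectors, one per distinct DO
#' @export
dos_from_sors <- function(net, sor_set) {
  out <- list()
  seen <- character(0)
  for (s in sor_set$sors) {
    dmin <- min_do_of_sor(net, s$reactions)
    free <- setdiff(net$species, dmin)
    free <- free[vapply(free, function(sp) {
      supp <- supported_reactions(net, species_closure(net, sp))
      all(supp %in% s$reactions)
    }, TRUE)]
    subsets <- .all_subsets(free)
    for (ss in subsets) {
      d <- net$species[net$species %in% c(dmin, ss)]
      key <- paste(d, collapse = "\r")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- d
      }
    }
  }
  out
}

.all_subsets <- function(x) {
  if (!length(x)) return(list(character(0)))
  out <- list(character(0))
  for (el in x) {
    out <- c(out, lapply(out, function(s) c(s, el)))
  }
  out
}
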
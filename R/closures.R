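## ---------------------------------------------------------------------------
## Species closures and elementary reaction closures (ERCs)
## ---------------------------------------------------------------------------

#' Closure of a set of species
#'
#' The closure `clos(S)` is the least superset of `S` that is stable under
#' the network: whenever all support species of a reaction are present, its
#' products are present as well. It is computed as the fixed point of the
#' one-step operator that adds the products of all supported reactions;
#' monotonicity guarantees termination in at most `n_species(net)` rounds.
#'
#' @param net a `reaction_network`
#' @param species character vector of species ids (a set; duplicates are
#'   ignored)
#' @return character vector: the closure, in network species order
#' @export
#' @examples
#' net <- example_network("mirna")
#' species_closure(net, c("miR_gene", "TF2"))
species_closure <- function(net, species) {
  species <- unique(as.character(species))
  unknown <- setdiff(species, net$species)
  if (length(unknown)) stop("unknown species id(s): ", paste(unknown, collapse = ", "))
  present <- net$species %in% species
  names(present) <- net$species
  ## work-list fixed point: recheck reactions until no species is added
  repeat {
    added <- FALSE
    for (r in net$reactions) {
      if (all(present[names(r$reactants)])) {
        prods <- names(r$products)
        new <- prods[!present[prods]]
        if (length(new)) {
          present[new] <- TRUE
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  net$species[present]
}

#' Reactions supported by a species set
#'
#' @param net a `reaction_network`
#' @param species character vector of species ids
#' @return ids of all reactions whose support is contained in `species`
#'   (inflow reactions are supported by every set)
#' @export
supported_reactions <- function(net, species) {
  species <- unique(as.character(species))
  ids <- reaction_ids(net)
  ids[vapply(net$reactions, function(r) all(names(r$reactants) %in% species), TRUE)]
}

#' Elementary reaction closures
#'
#' The elementary reaction closure of a reaction `r` is the set of all
#' reactions whose support lies in the closure of `supp(r)` -- the
#' reactions that are unavoidably activated as soon as `r` is active. The
#' ERC of a reaction is unique and always contains the reaction itself.
#'
#' @param net a `reaction_network`
#' @return a named list (one entry per reaction) of objects with elements
#'   `root` (the reaction id), `reactions` (ids of the ERC members) and
#'   `species` (the species closure `clos(supp(root))`)
#' @export
#' @examples
#' ercs <- create_ercs(example_network("mirna"))
#' sort(ercs[["r3"]]$reactions)
create_ercs <- function(net) {
  out <- lapply(net$reactions, function(r) {
    clos <- species_closure(net, names(r$reactants))
    list(root = r$id,
         reactions = supported_reactions(net, clos),
         species = clos)
  })
  names(out) <- reaction_ids(net)
  out
}

#' Containment graph of the ERCs, transitively reduced
#'
#' ERC containment is a preorder: reactions with identical ERCs (for
#' example the two directions of a reversible reaction) are mutually
#' contained. These are collapsed into classes first; the strict
#' containment relation between classes is then transitively reduced to a
#' Hasse-style edge set, the compact representation used when emitting
#' reaction-closure constraints.
#'
#' @param ercs result of [create_ercs()]
#' @return an object of class `erc_graph`: `classes` is a list of
#'   character vectors (reactions with identical ERC, in network order),
#'   `class_of` maps reaction id to class index, `edges` is a 2-column
#'   integer matrix of class indices `(from, to)` meaning
#'   `ERC(to-class)` is strictly contained in `ERC(from-class)`
#' @export
erc_graph <- function(ercs) {
  m <- length(ercs)
  ids <- names(ercs)
  sets <- lapply(ercs, function(e) sort(e$reactions))
  keys <- vapply(sets, paste, "", collapse = "\r")
  class_idx <- match(keys, unique(keys))
  k <- max(0L, class_idx)
  classes <- split(ids, class_idx)
  names(classes) <- NULL
  ## strict containment between class representatives
  reps <- vapply(seq_len(k), function(ci) which(class_idx == ci)[1], 0L)
  contain <- matrix(FALSE, k, k)  # contain[a, b]: ERC(b) subset of ERC(a)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a != b) {
        contain[a, b] <- all(sets[[reps[b]]] %in% sets[[reps[a]]])
      }
    }
  }
  ## transitive reduction of a DAG: drop edges implied by a 2-step path
  reduced <- contain
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (reduced[a, b]) {
        via <- contain[a, ] & contain[, b]
        via[c(a, b)] <- FALSE
        if (any(via)) reduced[a, b] <- FALSE
      }
    }
  }
  edges <- which(reduced, arr.ind = TRUE)
  colnames(edges) <- c("from", "to")
  structure(
    list(classes = classes,
         class_of = stats::setNames(class_idx, ids),
         edges = edges[order(edges[, 1], edges[, 2]), , drop = FALSE],
         contains = contain),
    class = "erc_graph"
  )
}

#' @export
print.erc_graph <- function(x, ...) {
  cat("erc_graph:", length(x$classes), "ERC classes,", nrow(x$edges), "reduced edges\n")
  invisible(x)
}

#' Reachability of an `erc_graph`
#'
#' @param graph an `erc_graph`
#' @return logical class-by-class matrix: entry `(a, b)` is `TRUE` when
#'   the ERC of class `b` is strictly contained in the ERC of class `a`
#'   (i.e. `b` is reachable from `a` through reduced edges)
#' @export
erc_reachability <- function(graph) {
  k <- length(graph$classes)
  reach <- matrix(FALSE, k, k)
  if (nrow(graph$edges)) {
    adj <- matrix(FALSE, k, k)
    adj[graph$edges] <- TRUE
    reach <- adj
    repeat {
      nxt <- reach | (reach %*% adj > 0)
      if (identical(nxt, reach)) break
      reach <- nxt
    }
  }
  reach
}

#' Export the reduced ERC graph as Graphviz DOT
#'
#' @param graph an `erc_graph`
#' @param path optional output file
#' @return the DOT lines, invisibly when `path` is given
#' @export
erc_graph_dot <- function(graph, path = NULL) {
  lab <- vapply(graph$classes, paste, "", collapse = ", ")
  lines <- c("digraph ercs {",
             "  node [shape=box];",
             sprintf("  c%d [label=\"%s\"];", seq_along(lab), lab),
             if (nrow(graph$edges)) {
               sprintf("  c%d -> c%d;", graph$edges[, 1], graph$edges[, 2])
             },
             "}")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
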
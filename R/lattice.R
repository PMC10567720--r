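## ---------------------------------------------------------------------------
## Lattices of SORs and DOs
## ---------------------------------------------------------------------------

#' Build a lattice from a collection of sets
#'
#' Orders the sets by inclusion and computes the Hasse edges (the
#' transitive reduction of strict inclusion) together with per-node "new
#' element" annotations: an element is new in a node when it appears in no
#' strict sub-node of the lattice. Duplicate sets are deduplicated with a
#' warning.
#'
#' @param sets list of character vectors
#' @param annotations optional list (same length/order as the deduplicated
#'   `sets`) of per-node metadata carried through to [export_dot()];
#'   recognised fields: `is_organization`, `label_lines`,
#'   `same_species_with` (indices of other nodes)
#' @return an object of class `do_lattice_graph` with `nodes` (list of
#'   sorted character vectors), `edges` (2-column matrix of node indices,
#'   `from` a strict subset of `to` with nothing in between), `new`
#'   (list of per-node new elements) and `annotations`
#' @export
build_lattice <- function(sets, annotations = NULL) {
  keys <- vapply(sets, function(s) paste(sort(s), collapse = "\r"), "")
  if (anyDuplicated(keys)) {
    warning("duplicate nodes removed from lattice input")
    keep <- !duplicated(keys)
    sets <- sets[keep]
    if (!is.null(annotations)) annotations <- annotations[keep]
  }
  k <- length(sets)
  sets <- lapply(sets, sort)
  ## strict subset matrix: sub[i, j] = TRUE iff sets[[i]] strictly inside sets[[j]]
  sub <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j && length(sets[[i]]) < length(sets[[j]]) &&
          all(sets[[i]] %in% sets[[j]])) {
        sub[i, j] <- TRUE
      }
    }
  }
  hasse <- sub
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (hasse[i, j] && any(sub[i, ] & sub[, j])) hasse[i, j] <- FALSE
    }
  }
  edges <- which(hasse, arr.ind = TRUE)
  colnames(edges) <- c("from", "to")
  newel <- lapply(seq_len(k), function(j) {
    below <- unique(unlist(sets[sub[, j]]))
    setdiff(sets[[j]], below)
  })
  structure(list(nodes = sets, edges = edges[order(edges[, 2], edges[, 1]), ,
                                             drop = FALSE],
                 subset = sub, new = newel, annotations = annotations),
            class = "do_lattice_graph")
}

#' @export
print.do_lattice_graph <- function(x, ...) {
  cat("lattice:", length(x$nodes), "nodes,", nrow(x$edges), "Hasse edges\n")
  invisible(x)
}

#' Supremum of two SORs
#'
#' The supremum of two SORs is their union: the disjoint juxtaposition of
#' their compartmentalizations realises the union with the summed witness
#' flux, so the union is again a SOR.
#'
#' @param r1,r2 character vectors of reaction ids
#' @return character vector, the union
#' @export
sor_supremum <- function(r1, r2) sort(union(r1, r2))

#' Infimum of two SORs
#'
#' The infimum is the union of all SORs contained in the intersection
#' `r1 & r2`, taken over a complete enumeration; it always contains
#' `R_min` and is itself a SOR.
#'
#' @param r1,r2 character vectors of reaction ids
#' @param sors a complete collection of the network's SORs: a `sor_set`
#'   from [all_sors()] or a list of reaction-id vectors
#' @return character vector of reaction ids
#' @export
sor_infimum <- function(r1, r2, sors) {
  if (inherits(sors, "sor_set")) sors <- lapply(sors$sors, `[[`, "reactions")
  inter <- intersect(r1, r2)
  inside <- sors[vapply(sors, function(s) all(s %in% inter), TRUE)]
  sort(unique(unlist(inside)))
}

#' Annotated lattice of the SORs of a network
#'
#' Convenience wrapper: enumerates (or reuses) the SORs, builds the
#' inclusion lattice and attaches the display annotations used by the
#' annotated DOT export: per node the new reactions, overproduced
#' species, minimal DO, minimal compartmentalization (vertical-bar
#' notation) and the organization flag; plus links between SORs whose
#' minimal DOs have identical species sets.
#'
#' @param net a `reaction_network`
#' @param sors optional precomputed annotated `sor_set`
#' @param config an [enumeration_config()]
#' @return a `do_lattice_graph`
#' @export
sor_lattice <- function(net, sors = NULL, config = enumeration_config()) {
  if (is.null(sors)) sors <- all_sors(net, config, annotate = TRUE)
  recs <- sors$sors
  sets <- lapply(recs, `[[`, "reactions")
  dmins <- lapply(recs, `[[`, "min_do")
  dkeys <- vapply(dmins, paste, "", collapse = "\r")
  ann <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    list(
      is_organization = isTRUE(r$is_organization),
      min_do = r$min_do,
      overproduced = r$overproduced,
      compartmentalization = r$min_compartments,
      label_lines = c(
        paste0("S: {", paste(sort(r$reactions), collapse = " "), "}  OP: {",
               paste(r$overproduced, collapse = " "), "}"),
        paste0("D: {", paste(r$min_do, collapse = " "), "}"),
        paste0("{", paste(vapply(r$min_compartments, paste, "", collapse = " "),
                          collapse = " | "), "}")
      ),
      same_species_with = setdiff(which(dkeys == dkeys[i]), i)
    )
  })
  build_lattice(sets, ann)
}

#' Lattice of the DOs of a network
#'
#' @param net a `reaction_network`
#' @param dos optional precomputed `do_set`
#' @param config an [enumeration_config()]
#' @return a `do_lattice_graph`; boxes/ellipses in the export follow the
#'   organization flag of each DO
#' @export
do_lattice <- function(net, dos = NULL, config = enumeration_config()) {
  if (is.null(dos)) dos <- all_dos(net, config)
  recs <- dos$dos
  sets <- lapply(recs, `[[`, "species")
  ann <- lapply(recs, function(d) {
    list(is_organization = isTRUE(d$is_organization),
         label_lines = paste0("{", paste(sort(d$species), collapse = " "), "}"),
         same_species_with = integer(0))
  })
  build_lattice(sets, ann)
}

#' Export a lattice as Graphviz DOT
#'
#' Nodes are drawn as boxes when their annotation flags an organization
#' and as ellipses otherwise; elements that are new in a node (present in
#' no strict sub-node) are coloured green in the label; Hasse edges are
#' plain, and pairs of nodes flagged as representing the same species set
#' are linked in red. Compartmentalizations use the vertical-bar notation
#' `{s1 s2 | s1 s3}`.
#'
#' @param lattice a `do_lattice_graph`
#' @param path optional output file
#' @return the DOT lines (invisibly when `path` is given)
#' @export
export_dot <- function(lattice, path = NULL) {
  k <- length(lattice$nodes)
  lines <- c("graph lattice {", "  rankdir=BT;")
  for (i in seq_len(k)) {
    a <- if (!is.null(lattice$annotations)) lattice$annotations[[i]] else NULL
    shape <- if (!is.null(a) && isTRUE(a$is_organization)) "box" else "ellipse"
    lab <- if (!is.null(a) && !is.null(a$label_lines)) {
      a$label_lines
    } else {
      paste0("{", paste(lattice$nodes[[i]], collapse = " "), "}")
    }
    lab <- paste(vapply(lab, .dot_mark_new, "", new = lattice$new[[i]]),
                 collapse = "<br/>")
    lines <- c(lines, sprintf("  n%d [shape=%s, label=<%s>];", i, shape, lab))
  }
  if (nrow(lattice$edges)) {
    lines <- c(lines, sprintf("  n%d -- n%d;",
                              lattice$edges[, 1], lattice$edges[, 2]))
  }
  ## red links between nodes representing the same species set
  if (!is.null(lattice$annotations)) {
    done <- matrix(FALSE, k, k)
    for (i in seq_len(k)) {
      for (j in lattice$annotations[[i]]$same_species_with) {
        a <- min(i, j); b <- max(i, j)
        if (!done[a, b]) {
          done[a, b] <- TRUE
          lines <- c(lines,
                     sprintf("  n%d -- n%d [color=red, constraint=false];", a, b))
        }
      }
    }
  }
  lines <- c(lines, "}")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

## colour tokens that are new elements green inside an HTML-ish DOT label
.dot_mark_new <- function(line, new) {
  line <- gsub("&", "&amp;", line, fixed = TRUE)
  line <- gsub("<", "&lt;", line, fixed = TRUE)
  line <- gsub(">", "&gt;", line, fixed = TRUE)
  if (!length(new)) return(line)
  tokens <- strsplit(line, " ", fixed = TRUE)[[1]]
  bare <- gsub("[{}]", "", tokens)
  hit <- bare %in% new & nzchar(bare)
  tokens[hit] <- vapply(which(hit), function(i) {
    sub(bare[i], paste0("<font color=\"darkgreen\">", bare[i], "</font>"),
        tokens[i], fixed = TRUE)
  }, "")
  paste(tokens, collapse = " ")
}

#' Serialise a lattice to JSON
#'
#' @param lattice a `do_lattice_graph`
#' @param path optional output file
#' @return JSON string (invisibly when `path` is given)
#' @export
lattice_json <- function(lattice, path = NULL) {
  obj <- list(
    nodes = lapply(seq_along(lattice$nodes), function(i) {
      a <- if (!is.null(lattice$annotations)) lattice$annotations[[i]] else NULL
      list(elements = lattice$nodes[[i]], new = lattice$new[[i]],
           is_organization = if (!is.null(a)) isTRUE(a$is_organization) else NA)
    }),
    edges = if (nrow(lattice$edges)) {
      lapply(seq_len(nrow(lattice$edges)), function(e) {
        as.list(lattice$edges[e, ])
      })
    } else {
      list()
    }
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
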
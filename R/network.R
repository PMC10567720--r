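#' dosor: distributed organizations and organizational reaction sets
#'
#' Structural analysis of reaction networks in the sense of chemical
#' organization theory: closures and elementary reaction closures,
#' enumeration of all sets of organizational reactions (SORs) and all
#' distributed organizations (DOs) by mixed-integer programming with
#' integer cuts, maximal compartments and minimal compartmentalizations,
#' and annotated lattices of the results.
#'
#' @keywords internal
"_PACKAGE"

## ---------------------------------------------------------------------------
## Reaction network container
## ---------------------------------------------------------------------------

#' Construct a reaction network
#'
#' A reaction network is a finite set of species together with a finite set
#' of reactions `sum_i a_ij s_i -> sum_i b_ij s_i` with non-negative integer
#' stoichiometric coefficients. Species and reactions keep the order of
#' first occurrence; set-valued results elsewhere in the package never
#' depend on this order.
#'
#' @param reactions a list of reactions; each reaction is a list with
#'   elements `id` (unique string), `reactants` and `products` (named
#'   integer vectors, names are species ids, values are coefficients > 0;
#'   an empty or `NULL` vector denotes an empty side). A reaction with
#'   empty reactant side is an inflow reaction.
#' @param species optional character vector of species ids fixing the
#'   species universe and order; defaults to first occurrence over the
#'   reactions. Species referenced by a reaction but missing here is an
#'   error.
#' @param species_names optional named character vector of human-readable
#'   names, keyed by species id.
#'
#' @return an object of class `reaction_network` with elements `species`
#'   (character vector), `species_names`, and `reactions` (named list).
#' @export
#' @examples
#' net <- reaction_network(list(
#'   list(id = "r1", reactants = c(A = 1), products = c(A = 1, B = 1)),
#'   list(id = "r2", reactants = c(B = 1), products = NULL)
#' ))
#' n_species(net); n_reactions(net)
reaction_network <- function(reactions = list(), species = NULL,
                             species_names = NULL) {
  stopifnot(is.list(reactions))
  reactions <- lapply(reactions, function(r) {
    if (is.null(r$id) || !nzchar(r$id)) stop("every reaction needs a non-empty id")
    r$reactants <- .coef_vec(r$reactants, r$id)
    r$products <- .coef_vec(r$products, r$id)
    r[c("id", "reactants", "products")]
  })
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate reaction ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(reactions) <- ids
  seen <- unique(unlist(lapply(reactions, function(r) {
    c(names(r$reactants), names(r$products))
  }), use.names = FALSE))
  if (is.null(species)) {
    species <- if (is.null(seen)) character() else seen
  } else {
    species <- as.character(species)
    if (anyDuplicated(species)) stop("duplicate species ids")
    missing <- setdiff(seen, species)
    if (length(missing)) {
      stop("reactions reference unknown species: ", paste(missing, collapse = ", "))
    }
  }
  if (any(!nzchar(species))) stop("species ids must be non-empty")
  structure(
    list(species = species, species_names = species_names, reactions = reactions),
    class = "reaction_network"
  )
}

## normalise one side of a reaction to a named non-negative integer vector
.coef_vec <- function(x, rid) {
  if (is.null(x) || length(x) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("reaction ", rid, ": coefficients must be named by species id")
  }
  if (anyDuplicated(names(x))) {
    stop("reaction ", rid, ": a species appears more than once on one side")
  }
  v <- as.numeric(x)
  if (any(v < 0)) stop("reaction ", rid, ": negative stoichiometric coefficient")
  if (any(abs(v - round(v)) > 1e-9)) {
    stop("non-integer stoichiometry in reaction ", rid, " for species ",
         paste(names(x)[abs(v - round(v)) > 1e-9], collapse = ", "))
  }
  v <- as.integer(round(v))
  keep <- v > 0
  stats::setNames(v[keep], names(x)[keep])
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network:", length(x$species), "species,",
      length(x$reactions), "reactions\n")
  for (r in x$reactions) {
    cat(" ", r$id, ": ", .side_str(r$reactants), " -> ",
        .side_str(r$products), "\n", sep = "")
  }
  invisible(x)
}

.side_str <- function(side) {
  if (!length(side)) return("0")
  paste(ifelse(side == 1, names(side), paste(side, names(side))), collapse = " + ")
}

#' Number of species / reactions of a network
#' @param net a `reaction_network`
#' @return an integer
#' @export
n_species <- function(net) length(net$species)

#' @rdname n_species
#' @export
n_reactions <- function(net) length(net$reactions)

#' Reaction ids of a network
#' @param net a `reaction_network`
#' @return character vector in network order
#' @export
reaction_ids <- function(net) names(net$reactions)

#' Support and product sets of a reaction
#'
#' The support of a reaction is the set of species with positive reactant
#' coefficient, its products the species with positive product coefficient.
#'
#' @param net a `reaction_network`
#' @param rid a reaction id
#' @return character vector of species ids
#' @export
reaction_support <- function(net, rid) {
  names(.get_reaction(net, rid)$reactants)
}

#' @rdname reaction_support
#' @export
reaction_products <- function(net, rid) {
  names(.get_reaction(net, rid)$products)
}

.get_reaction <- function(net, rid) {
  r <- net$reactions[[rid]]
  if (is.null(r)) stop("unknown reaction id: ", rid)
  r
}

#' Inflow reactions of a network
#'
#' A reaction with empty support is an inflow reaction; it is active under
#' every feasible flux and therefore contained in every SOR.
#'
#' @param net a `reaction_network`
#' @return character vector of reaction ids (possibly empty)
#' @export
inflow_reactions <- function(net) {
  ids <- reaction_ids(net)
  ids[vapply(net$reactions, function(r) length(r$reactants) == 0L, TRUE)]
}

#' Stoichiometric matrix
#'
#' Returns the n x m integer matrix `N` with `N[i, j] = b_ij - a_ij`
#' (products minus reactants). Catalysts, appearing with equal coefficient
#' on both sides, contribute zero.
#'
#' @param net a `reaction_network`
#' @return integer matrix with species ids as row names and reaction ids as
#'   column names; `0 x 0` for an empty network
#' @export
stoichiometric_matrix <- function(net) {
  n <- length(net$species)
  m <- length(net$reactions)
  N <- matrix(0L, n, m, dimnames = list(net$species, names(net$reactions)))
  for (j in seq_len(m)) {
    r <- net$reactions[[j]]
    N[names(r$products), j] <- N[names(r$products), j] + r$products
    N[names(r$reactants), j] <- N[names(r$reactants), j] - r$reactants
  }
  N
}

## ---------------------------------------------------------------------------
## Plain-text reaction notation
## ---------------------------------------------------------------------------

#' Read a network from plain-text reaction notation
#'
#' One reaction per line, `id: 2 A + B -> C` style. Coefficients default
#' to 1; an empty side is written `0` or left blank (so `rx: -> A` is an
#' inflow and `ry: A -> 0` an outflow). Blank lines and lines starting
#' with `#` are ignored. Species are collected in first-occurrence order.
#'
#' @param text character vector of lines, or a single string with newlines
#' @param path path to a file in the same notation (exactly one of `text`
#'   and `path` must be given)
#' @return a `reaction_network`
#' @export
#' @examples
#' read_reaction_text(c("r1: A -> A + B", "r2: B -> 0"))
read_reaction_text <- function(text = NULL, path = NULL) {
  if (is.null(text) == is.null(path)) stop("give exactly one of `text` or `path`")
  if (!is.null(path)) text <- readLines(path, warn = FALSE)
  if (length(text) == 1 && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]
  reactions <- list()
  for (i in seq_along(text)) {
    line <- trimws(text[[i]])
    if (!nzchar(line) || startsWith(line, "#")) next
    m <- regmatches(line, regexec("^([^:]+):(.*)$", line))[[1]]
    if (length(m) != 3) stop("line ", i, ": expected 'id: reactants -> products'")
    rid <- trimws(m[2])
    body <- strsplit(m[3], "->", fixed = TRUE)[[1]]
    if (length(body) != 2) stop("line ", i, ": expected exactly one '->'")
    reactions[[length(reactions) + 1]] <- list(
      id = rid,
      reactants = .parse_side(body[1], i),
      products = .parse_side(body[2], i)
    )
  }
  reaction_network(reactions)
}

.parse_side <- function(s, lineno) {
  s <- trimws(s)
  if (!nzchar(s) || identical(s, "0")) return(NULL)
  terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  out <- numeric(0)
  for (t in terms) {
    if (!nzchar(t)) stop("line ", lineno, ": empty term")
    m <- regmatches(t, regexec("^([0-9]+)?\\s*([A-Za-z_][A-Za-z0-9_.]*)$", t))[[1]]
    if (length(m) != 3) stop("line ", lineno, ": cannot parse term '", t, "'")
    coef <- if (nzchar(m[2])) as.numeric(m[2]) else 1
    sp <- m[3]
    if (sp %in% names(out)) {
      stop("line ", lineno, ": species ", sp, " repeated on one side")
    }
    out[sp] <- coef
  }
  out
}

#' Write a network in plain-text reaction notation
#'
#' Inverse of [read_reaction_text()]: reading the written text yields a
#' network with identical species order, reactions and coefficients.
#'
#' @param net a `reaction_network`
#' @param path optional output file; if `NULL` the lines are returned
#' @return character vector of lines, invisibly when `path` is given
#' @export
write_reaction_text <- function(net, path = NULL) {
  lines <- vapply(net$reactions, function(r) {
    paste0(r$id, ": ", .side_str(r$reactants), " -> ", .side_str(r$products))
  }, "", USE.NAMES = FALSE)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

## ---------------------------------------------------------------------------
## Bundled example networks
## ---------------------------------------------------------------------------

#' Bundled example networks
#'
#' Two small fully specified reaction networks used throughout the
#' documentation and tests: `"mirna"`, a micro-RNA transcription-factor
#' interaction model (9 species, 11 irreversible reactions, no inflow),
#' and `"three_generator"`, an artificial model of three generators
#' A1..A3 with products B1..B3 and an intermediate D1 (7 species, 9
#' reactions).
#'
#' @param name `"mirna"` or `"three_generator"`
#' @return a `reaction_network`
#' @export
#' @examples
#' example_network("mirna")
example_network <- function(name = c("mirna", "three_generator")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".txt"), package = "dosor",
                      mustWork = TRUE)
  read_reaction_text(path = path)
}
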
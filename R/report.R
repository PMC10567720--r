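## ---------------------------------------------------------------------------
## One-call analysis and batch driver
## ---------------------------------------------------------------------------

#' Load a network from a path, fixture name or network object
#'
#' Paths ending in `.xml`/`.sbml` are read as SBML, anything else as
#' plain-text reaction notation; `"mirna"` and `"three_generator"` name
#' the bundled fixtures. The default, `NULL`, is the 3-generator model.
#'
#' @param input `NULL`, a `reaction_network`, a fixture name or a file path
#' @return a `reaction_network`
#' @export
load_network <- function(input = NULL) {
  if (is.null(input)) return(example_network("three_generator"))
  if (inherits(input, "reaction_network")) return(input)
  if (input %in% c("mirna", "three_generator")) return(example_network(input))
  if (!file.exists(input)) stop("no such file or fixture: ", input)
  if (tolower(tools::file_ext(input)) %in% c("xml", "sbml")) {
    read_sbml(input)
  } else {
    read_reaction_text(path = input)
  }
}

#' Analyse a reaction network end to end
#'
#' Computes the ERCs, enumerates the SORs (annotated with minimal DOs,
#' overproduction and minimal compartmentalizations) and optionally the
#' DOs, and summarises the result in a run report.
#'
#' @param input anything [load_network()] accepts
#' @param config an [enumeration_config()]
#' @param compute_dos also run the DO enumeration (default `TRUE`)
#' @param sor_dot,do_dot optional paths: write the annotated SOR / DO
#'   lattice as Graphviz DOT
#' @param model optional model identifier for the report; defaults to the
#'   input name
#' @param verbose log stage timings to `stderr`
#' @return an object of class `dosor_report`: counts (`n`, `m`,
#'   `n_sors`, `n_dos`, `n_organization_dos`, `n_genuine_dos`,
#'   `sor_min_compartments`), status flags (`truncated`, `timeout`),
#'   stage timings in seconds, and the full `sors` / `dos` objects
#' @export
#' @examples
#' rep <- analyze_network("mirna", compute_dos = FALSE)
#' rep$n_sors  # 8
analyze_network <- function(input = NULL, config = enumeration_config(),
                            compute_dos = TRUE, sor_dot = NULL, do_dot = NULL,
                            model = NULL, verbose = FALSE) {
  if (is.null(model)) {
    model <- if (is.character(input)) basename(input) else "network"
  }
  say <- function(...) if (verbose) message(sprintf(...))
  t_all <- proc.time()[["elapsed"]]
  net <- load_network(input)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  ercs <- create_ercs(net)
  timings["ercs"] <- tic() - t0
  say("[%s] %d ERCs (%.2fs)", model, length(ercs), timings["ercs"])
  t0 <- tic()
  sors <- all_sors(net, config, annotate = TRUE)
  timings["sors"] <- tic() - t0
  say("[%s] %d SORs, status %s (%.2fs)", model, length(sors$sors),
      sors$status, timings["sors"])
  dos <- NULL
  if (compute_dos) {
    t0 <- tic()
    dos <- all_dos(net, config)
    timings["dos"] <- tic() - t0
    say("[%s] %d DOs, status %s (%.2fs)", model, length(dos$dos),
        dos$status, timings["dos"])
  }
  if (!is.null(sor_dot)) export_dot(sor_lattice(net, sors), sor_dot)
  if (!is.null(do_dot) && !is.null(dos)) export_dot(do_lattice(net, dos), do_dot)
  timings["total"] <- tic() - t_all
  comp <- vapply(sors$sors, `[[`, 0L, "n_compartments")
  names(comp) <- vapply(sors$sors, function(s) {
    paste(sort(s$reactions), collapse = "+")
  }, "")
  statuses <- c(sors$status, if (!is.null(dos)) dos$status)
  structure(list(
    model = model,
    n = n_species(net), m = n_reactions(net),
    n_sors = length(sors$sors),
    n_organization_sors = sum(vapply(sors$sors, `[[`, TRUE, "is_organization")),
    n_dos = if (is.null(dos)) NA_integer_ else length(dos$dos),
    n_organization_dos = if (is.null(dos)) NA_integer_ else
      sum(vapply(dos$dos, `[[`, TRUE, "is_organization")),
    n_genuine_dos = if (is.null(dos)) NA_integer_ else
      sum(vapply(dos$dos, `[[`, TRUE, "is_genuine")),
    sor_min_compartments = comp,
    truncated = "truncated" %in% statuses,
    timeout = "timeout" %in% statuses,
    timings = timings,
    network = net, ercs = ercs, sors = sors, dos = dos
  ), class = "dosor_report")
}

#' @export
print.dosor_report <- function(x, ...) {
  cat("dosor_report [", x$model, "]: n=", x$n, " m=", x$m,
      " SORs=", x$n_sors, " (", x$n_organization_sors, " organizations)",
      sep = "")
  if (!is.na(x$n_dos)) {
    cat(" DOs=", x$n_dos, " (", x$n_genuine_dos, " genuine)", sep = "")
  }
  if (x$truncated) cat(" [truncated]")
  if (x$timeout) cat(" [timeout]")
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.dosor_report <- function(x, ...) {
  data.frame(model = x$model, n = x$n, m = x$m, n_sors = x$n_sors,
             n_organization_sors = x$n_organization_sors,
             n_dos = x$n_dos, n_organization_dos = x$n_organization_dos,
             n_genuine_dos = x$n_genuine_dos,
             max_min_compartments = if (length(x$sor_min_compartments))
               max(x$sor_min_compartments) else 0L,
             truncated = x$truncated, timeout = x$timeout,
             seconds = unname(x$timings["total"]),
             stringsAsFactors = FALSE)
}

#' Analyse a directory of models
#'
#' Runs [analyze_network()] on every matching file; a failure in one model
#' is recorded and does not stop the batch.
#'
#' @param dir directory containing SBML (`.xml`/`.sbml`) or plain-text
#'   (`.txt`) models
#' @param pattern file-name regexp, default all three extensions
#' @param config an [enumeration_config()]; set `time_limit` for a
#'   per-model cap
#' @param compute_dos per-model DO enumeration
#' @param csv optional path for the aggregate CSV
#' @return list with `reports` (per successful model), `errors` (named
#'   character messages) and `summary` (data frame, one row per success)
#' @export
analyze_directory <- function(dir, pattern = "\\.(xml|sbml|txt)$",
                              config = enumeration_config(),
                              compute_dos = TRUE, csv = NULL) {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  reports <- list()
  errors <- character(0)
  for (f in files) {
    res <- tryCatch(
      analyze_network(f, config = config, compute_dos = compute_dos),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[basename(f)] <- conditionMessage(res)
    } else {
      reports[[basename(f)]] <- res
    }
  }
  summary <- if (length(reports)) {
    do.call(rbind, lapply(reports, as.data.frame))
  } else {
    data.frame()
  }
  rownames(summary) <- NULL
  if (!is.null(csv)) utils::write.csv(summary, csv, row.names = FALSE)
  list(reports = reports, errors = errors, summary = summary)
}
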